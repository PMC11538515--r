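#' Profile similarity metrics
#'
#' `cosine_similarity(a, b)` is `sum(a*b) / (||a|| ||b||)`;
#' `rmse(a, b)` is `sqrt(mean((a-b)^2))`; `mape(a, b)` is
#' `mean(|a-b| / |a|)` with `a` the reference (real) profile — entries
#' where the reference is zero are excluded and their count attached as
#' attribute `"n_excluded"`.
#'
#' @param a Reference (real) profile.
#' @param b Comparison (synthetic) profile, same length.
#' @return A scalar.
#' @export
cosine_similarity <- function(a, b) {
  stopifnot(length(a) == length(b))
  na <- sqrt(sum(a^2))
  nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0)
    stop("cosine similarity undefined for a zero-norm vector", call. = FALSE)
  sum(a * b) / (na * nb)
}

#' @rdname cosine_similarity
#' @export
rmse <- function(a, b) {
  stopifnot(length(a) == length(b))
  sqrt(mean((a - b)^2))
}

#' @rdname cosine_similarity
#' @export
mape <- function(a, b) {
  stopifnot(length(a) == length(b))
  keep <- a != 0
  out <- mean(abs(a[keep] - b[keep]) / abs(a[keep]))
  attr(out, "n_excluded") <- sum(!keep)
  out
}

metric_fun <- function(metric) {
  switch(metric, cosine = cosine_similarity, rmse = rmse, mape = mape,
         stop("unknown metric '", metric, "'", call. = FALSE))
}

#' Negative-control similarity distribution
#'
#' The baseline a translator must beat: the chosen metric computed between
#' unordered pairs of *real* profiles within one organ, excluding
#' biological duplicates (pairs sharing compound, dose and time). When the
#' number of eligible pairs exceeds `max_pairs`, a seeded subsample is
#' used; otherwise the enumeration is exhaustive.
#'
#' @param expression Genes x samples log2 matrix.
#' @param metadata Sample metadata tibble.
#' @param organ `"liver"` or `"kidney"`.
#' @param metric `"cosine"`, `"rmse"` or `"mape"`.
#' @param max_pairs Cap on evaluated pairs.
#' @param seed Seed for the subsample.
#' @return Tibble with columns `sample_a`, `sample_b`, `value`.
#' @export
negative_control_distribution <- function(expression, metadata, organ,
                                          metric = "cosine",
                                          max_pairs = 1e5, seed = 1L) {
  fn <- metric_fun(metric)
  meta <- dplyr::filter(metadata, .data$organ == !!organ,
                        .data$sample_id %in% colnames(expression))
  if (nrow(meta) < 2L)
    stop("need at least 2 profiles in organ '", organ, "'", call. = FALSE)
  key <- treatment_key(meta)
  cmb <- utils::combn(nrow(meta), 2L)
  eligible <- which(key[cmb[1L, ]] != key[cmb[2L, ]])
  if (!length(eligible))
    stop("no eligible non-duplicate pairs in organ '", organ, "'",
         call. = FALSE)
  if (length(eligible) > max_pairs)
    eligible <- with_seed(seed, sample(eligible, max_pairs))
  a <- meta$sample_id[cmb[1L, eligible]]
  b <- meta$sample_id[cmb[2L, eligible]]
  value <- vapply(seq_along(a), function(i)
    as.numeric(fn(expression[, a[i]], expression[, b[i]])), 0)
  tibble::tibble(sample_a = a, sample_b = b, value = value)
}

#' Per-pair agreement between synthetic and matched real profiles
#'
#' Column i of `synthetic` is scored against column i of `real` with
#' cosine, RMSE and MAPE, and each metric is compared against the
#' negative-control distribution of the same organ by a Welch two-sample
#' t-test. Both the mean over per-pair values and the pooled view are in
#' `summary`.
#'
#' @param synthetic,real Genes x n matrices in matched column order
#'   (synthetic profile i corresponds to real profile i).
#' @param expression Real genes x samples matrix used to build the
#'   negative control (usually the full organ matrix).
#' @param metadata Sample metadata for `expression`.
#' @param organ Organ of the real profiles.
#' @param max_pairs,seed Passed to [negative_control_distribution()].
#' @return An `agreement_report`: list with `per_pair`, `baseline` and
#'   `summary` tibbles. `autoplot()` draws the violin comparison.
#' @export
agreement_report <- function(synthetic, real, expression, metadata, organ,
                             max_pairs = 1e5, seed = 1L) {
  stopifnot(ncol(synthetic) == ncol(real), nrow(synthetic) == nrow(real))
  per_pair <- tibble::tibble(
    sample_id = colnames(real),
    cosine = vapply(seq_len(ncol(real)), function(i)
      cosine_similarity(real[, i], synthetic[, i]), 0),
    rmse = vapply(seq_len(ncol(real)), function(i)
      rmse(real[, i], synthetic[, i]), 0),
    mape = vapply(seq_len(ncol(real)), function(i)
      as.numeric(mape(real[, i], synthetic[, i])), 0))
  baselines <- lapply(c(cosine = "cosine", rmse = "rmse", mape = "mape"),
                      function(m)
                        negative_control_distribution(expression, metadata,
                                                      organ, m, max_pairs, seed))
  baseline <- dplyr::bind_rows(baselines, .id = "metric")
  summary <- purrr::map_dfr(c("cosine", "rmse", "mape"), function(m) {
    x <- per_pair[[m]]
    y <- baselines[[m]]$value
    p <- tryCatch(stats::t.test(x, y)$p.value, error = function(e) NA_real_)
    tibble::tibble(metric = m, synthetic_mean = mean(x), synthetic_sd = stats::sd(x),
                   baseline_mean = mean(y), baseline_sd = stats::sd(y),
                   n_pairs = length(x), n_baseline = length(y),
                   p_value = p)
  })
  structure(list(per_pair = per_pair, baseline = baseline, summary = summary,
                 organ = organ),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat("<agreement_report>", x$organ, "-", nrow(x$per_pair), "matched pairs\n")
  print(x$summary)
  invisible(x)
}

#' @rdname agreement_report
#' @param x An `agreement_report`.
#' @param ... Unused.
#' @export
glance.agreement_report <- function(x, ...) {
  tidyr::pivot_wider(x$summary[c("metric", "synthetic_mean", "baseline_mean",
                                 "p_value")],
                     names_from = "metric",
                     values_from = c("synthetic_mean", "baseline_mean",
                                     "p_value"))
}

#' @rdname agreement_report
#' @export
tidy.agreement_report <- function(x, ...) x$summary

#' Replicate-averaged condition profiles
#'
#' Averages biological replicates within each (compound, organ, dose,
#' time) treatment condition — the unit at which fold changes, gene-level
#' comparisons and the necrosis classifier operate.
#'
#' @param expression Genes x samples log2 matrix.
#' @param metadata Sample metadata tibble.
#' @return List with `profiles` (genes x conditions matrix) and
#'   `conditions` (tibble: condition, compound, organ, dose, time_days,
#'   n_replicates).
#' @export
condition_profiles <- function(expression, metadata) {
  meta <- dplyr::filter(metadata, .data$sample_id %in% colnames(expression))
  key <- condition_key(meta)
  groups <- split(meta$sample_id, key)
  cond <- meta[!duplicated(key), c("compound", "organ", "dose", "time_days")]
  cond$condition <- key[!duplicated(key)]
  cond$n_replicates <- lengths(groups)[cond$condition]
  prof <- vapply(cond$condition, function(k)
    rowMeans(expression[, groups[[k]], drop = FALSE]), numeric(nrow(expression)))
  colnames(prof) <- cond$condition
  list(profiles = prof,
       conditions = tibble::as_tibble(cond[c("condition", "compound", "organ",
                                             "dose", "time_days",
                                             "n_replicates")]))
}

new_gene_variability <- function(tbl, n_excluded) {
  structure(list(values = tbl, n_excluded = n_excluded),
            class = "gene_variability")
}

#' @export
print.gene_variability <- function(x, ...) {
  cat("<gene_variability>", nrow(x$values), "gene-treatment entries,",
      x$n_excluded, "excluded (zero denominator)\n")
  invisible(x)
}

#' Gene-level variability among biological duplicates
#'
#' The experimental yardstick for translator accuracy: for every
#' treatment condition with at least two replicate rats, each unordered
#' replicate pair contributes `v = (x - x') / x` per gene, where `x` is
#' the first replicate (reference) and `x'` the other. Zero-reference
#' entries are excluded and counted.
#'
#' @param expression Genes x samples log2 matrix.
#' @param metadata Sample metadata tibble.
#' @param organ Organ to analyse.
#' @return A `gene_variability` object (tibble `values` with columns
#'   `gene`, `condition`, `statistic`, `v`, plus exclusion count).
#' @export
duplicate_variability <- function(expression, metadata, organ) {
  meta <- dplyr::filter(metadata, .data$organ == !!organ,
                        .data$sample_id %in% colnames(expression))
  key <- condition_key(meta)
  groups <- split(meta$sample_id, key)
  groups <- groups[lengths(groups) >= 2L]
  if (!length(groups))
    stop("no condition with >= 2 replicates in organ '", organ, "'",
         call. = FALSE)
  n_excl <- 0L
  rows <- purrr::imap(groups, function(ids, k) {
    cmb <- utils::combn(ids, 2L)
    purrr::map_dfr(seq_len(ncol(cmb)), function(j) {
      x <- expression[, cmb[1L, j]]
      xp <- expression[, cmb[2L, j]]
      keep <- x != 0
      n_excl <<- n_excl + sum(!keep)
      tibble::tibble(gene = rownames(expression)[keep], condition = k,
                     statistic = paste0("duplicate_", organ),
                     v = (x[keep] - xp[keep]) / x[keep])
    })
  })
  new_gene_variability(dplyr::bind_rows(rows), n_excl)
}

#' Gene-level synthetic-vs-real variability, within and between organs
#'
#' Works on condition-level (replicate-averaged) profiles over a matched
#' (gene x treatment) grid. Within-organ variability is
#' `(x - x') / x` per organ, where `x` is the real value and `x'` the
#' synthetic one. Between-organ variability measures how well the
#' liver-kidney gene distance is preserved:
#' `((x - y) - (x' - y)) / ((x + y) / 2)` when the liver side is
#' synthetic, and `((x - y) - (x - y')) / ((x + y) / 2)` when the kidney
#' side is (x = real liver, y = real kidney). Zero-denominator cells are
#' excluded and counted.
#'
#' @param real_liver,synth_liver,real_kidney,synth_kidney Genes x
#'   treatment matrices with identical dimnames.
#' @return A `gene_variability` with statistics `in_liver`, `in_kidney`,
#'   `between_synth_liver`, `between_synth_kidney`.
#' @seealso [fraction_within()]
#' @export
gene_level_comparison <- function(real_liver, synth_liver,
                                  real_kidney, synth_kidney) {
  mats <- list(real_liver, synth_liver, real_kidney, synth_kidney)
  dn <- dimnames(real_liver)
  ok <- vapply(mats, function(m) identical(dimnames(m), dn), TRUE)
  if (!all(ok))
    stop("all four matrices must share the same gene x treatment grid",
         call. = FALSE)
  n_excl <- 0L
  long <- function(num, den, statistic) {
    keep <- den != 0
    n_excl <<- n_excl + sum(!keep)
    idx <- which(keep, arr.ind = TRUE)
    tibble::tibble(gene = dn[[1]][idx[, 1]], condition = dn[[2]][idx[, 2]],
                   statistic = statistic, v = (num / den)[keep])
  }
  x <- real_liver; xp <- synth_liver; y <- real_kidney; yp <- synth_kidney
  avg <- (x + y) / 2
  out <- dplyr::bind_rows(
    long(x - xp, x, "in_liver"),
    long(y - yp, y, "in_kidney"),
    long((x - y) - (xp - y), avg, "between_synth_liver"),
    long((x - y) - (x - yp), avg, "between_synth_kidney"))
  new_gene_variability(out, n_excl)
}

#' Fraction of gene-level variability entries inside a bound
#'
#' Strict inequality: the fraction of entries with `|v| < bound`,
#' optionally per statistic or restricted to a gene subset (e.g. the
#' Important Genes).
#'
#' @param variability A `gene_variability`.
#' @param bound Variation bound (default 0.1 = "within 10%").
#' @param genes Optional gene-id subset.
#' @param by_statistic Return one row per statistic instead of a single
#'   pooled fraction.
#' @return A scalar, or a tibble when `by_statistic = TRUE`.
#' @export
fraction_within <- function(variability, bound = 0.1, genes = NULL,
                            by_statistic = FALSE) {
  stopifnot(inherits(variability, "gene_variability"))
  vals <- variability$values
  if (!nrow(vals)) stop("empty variability table", call. = FALSE)
  if (!is.null(genes)) vals <- vals[vals$gene %in% genes, ]
  if (by_statistic) {
    dplyr::summarise(dplyr::group_by(vals, .data$statistic),
                     fraction = mean(abs(.data$v) < bound), n = dplyr::n(),
                     .groups = "drop")
  } else {
    mean(abs(vals$v) < bound)
  }
}

#' Genes with a strong response in at least one treatment
#'
#' The "Important Genes": genes whose absolute log2 fold change exceeds
#' `threshold` (strictly) in at least one treatment condition.
#'
#' @param fold_changes Genes x treatment matrix of log2 fold changes, or a
#'   tibble from [fold_changes()].
#' @param threshold Absolute log2-fold-change cut (default 1).
#' @return Character vector of gene ids.
#' @export
important_genes <- function(fold_changes, threshold = 1) {
  if (inherits(fold_changes, "fold_change_table"))
    fold_changes <- fc_matrix(fold_changes)
  stopifnot(is.matrix(fold_changes))
  mx <- apply(abs(fold_changes), 1L, max)
  rownames(fold_changes)[mx > threshold]
}

#' 2-D embedding of expression profiles
#'
#' UMAP projection of one or more profile matrices (e.g. real and
#' synthetic side by side) for visual agreement checks. Seeded and
#' single-threaded, so a fixed seed reproduces coordinates exactly.
#'
#' @param matrices A genes x samples matrix or named list of such matrices
#'   sharing the same genes.
#' @param labels Optional per-profile labels; defaults to the list names.
#' @param seed Seed.
#' @param n_neighbors UMAP neighbourhood size (capped at n - 1).
#' @return Tibble: `sample_id`, `label`, `dim1`, `dim2`.
#' @export
embed_2d <- function(matrices, labels = NULL, seed = 1L, n_neighbors = 15L) {
  if (is.matrix(matrices)) matrices <- list(profiles = matrices)
  combined <- do.call(cbind, matrices)
  n <- ncol(combined)
  if (n < 3L) stop("need at least 3 profiles to embed", call. = FALSE)
  if (is.null(labels))
    labels <- rep(names(matrices), vapply(matrices, ncol, 0L))
  stopifnot(length(labels) == n)
  coords <- with_seed(seed,
    uwot::umap(t(combined), n_neighbors = min(n_neighbors, n - 1L),
               n_threads = 1L, n_sgd_threads = 1L))
  tibble::tibble(sample_id = colnames(combined) %||% as.character(seq_len(n)),
                 label = labels,
                 dim1 = coords[, 1L], dim2 = coords[, 2L])
}
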