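#' Log2 fold changes per treatment condition
#'
#' Averages replicate rats within each treated condition and subtracts the
#' mean of the time-matched control group of the same compound and organ
#' (in log2 units, so the difference of means is the log2 fold change).
#' Synthetic treatment profiles are referenced against *real* controls by
#' passing the real data through `control_expression`/`control_metadata`;
#' conditions with no matching control group are skipped with a warning.
#'
#' @param expression Genes x samples log2 matrix of treated profiles (may
#'   include controls, which are never treated as "treatment" columns).
#' @param metadata Metadata for `expression`.
#' @param control_expression,control_metadata Where control groups come
#'   from; default the same matrix (the ordinary all-real analysis).
#' @return A `fold_change_table`: tibble with `gene`, `condition`,
#'   `compound`, `organ`, `dose`, `time_days`, `log2fc`. Use
#'   [fc_matrix()] for the genes x condition matrix view.
#' @export
fold_changes <- function(expression, metadata,
                         control_expression = expression,
                         control_metadata = metadata) {
  treated <- condition_profiles(expression, metadata)
  ctrl <- condition_profiles(control_expression, control_metadata)
  tc <- dplyr::filter(treated$conditions, .data$dose != "control")
  cc <- dplyr::filter(ctrl$conditions, .data$dose == "control")
  ctrl_key <- paste(cc$compound, cc$organ, cc$time_days, sep = "|")
  rows <- vector("list", nrow(tc))
  skipped <- character(0)
  for (i in seq_len(nrow(tc))) {
    k <- paste(tc$compound[i], tc$organ[i], tc$time_days[i], sep = "|")
    j <- match(k, ctrl_key)
    if (is.na(j)) {
      skipped <- c(skipped, tc$condition[i])
      next
    }
    fc <- treated$profiles[, tc$condition[i]] - ctrl$profiles[, cc$condition[j]]
    rows[[i]] <- tibble::tibble(gene = rownames(expression),
                                condition = tc$condition[i],
                                compound = tc$compound[i], organ = tc$organ[i],
                                dose = tc$dose[i], time_days = tc$time_days[i],
                                log2fc = fc)
  }
  if (length(skipped))
    warning("condition(s) without a time-matched control skipped: ",
            paste(skipped, collapse = ", "), call. = FALSE)
  out <- dplyr::bind_rows(rows)
  structure(list(values = out, skipped = skipped),
            class = "fold_change_table")
}

#' @rdname fold_changes
#' @param x A `fold_change_table`.
#' @export
fc_matrix <- function(x) {
  stopifnot(inherits(x, "fold_change_table"))
  wide <- tidyr::pivot_wider(x$values[c("gene", "condition", "log2fc")],
                             names_from = "condition", values_from = "log2fc")
  m <- as.matrix(wide[-1L])
  rownames(m) <- wide$gene
  m
}

#' @export
print.fold_change_table <- function(x, ...) {
  cat("<fold_change_table>", length(unique(x$values$gene)), "genes x",
      length(unique(x$values$condition)), "conditions")
  if (length(x$skipped)) cat(" (", length(x$skipped), "skipped)")
  cat("\n")
  invisible(x)
}

#' @rdname fold_changes
#' @param ... Unused.
#' @export
tidy.fold_change_table <- function(x, ...) x$values

#' Call differentially expressed genes per condition
#'
#' A gene is differential in a condition when its absolute log2 fold
#' change strictly exceeds `threshold` (so a fold change of exactly the
#' threshold is not called).
#'
#' @param fold_changes A [fold_changes()] table or genes x condition
#'   matrix.
#' @param threshold Positive log2-fold-change cut (default 1).
#' @return Named list of gene-id character vectors (one per condition),
#'   with the threshold attached as attribute `"threshold"`.
#' @export
call_degs <- function(fold_changes, threshold = 1) {
  stopifnot(threshold > 0)
  m <- if (inherits(fold_changes, "fold_change_table"))
    fc_matrix(fold_changes) else fold_changes
  out <- lapply(seq_len(ncol(m)), function(j)
    rownames(m)[abs(m[, j]) > threshold])
  names(out) <- colnames(m)
  attr(out, "threshold") <- threshold
  out
}

#' Calibrate the DEG threshold for synthetic fold changes
#'
#' Generated profiles have slightly compressed dynamics, so applying the
#' real-data threshold directly under- or over-calls DEGs. On matched
#' *training* conditions, this picks the synthetic threshold whose mean
#' per-condition DEG count is closest to the real data's mean count at
#' `real_threshold`; ties go to the smallest threshold.
#'
#' @param real_fc,synth_fc Fold-change tables (or matrices) over matched
#'   conditions; only shared condition names are used.
#' @param real_threshold DEG threshold for the real data (default 1).
#' @param grid Candidate thresholds (default 0.05-spaced in (0, 3]).
#' @return The calibrated threshold, with the grid trace attached as
#'   attribute `"trace"` (tibble: threshold, mean_deg_count, gap).
#' @export
calibrate_synthetic_threshold <- function(real_fc, synth_fc,
                                          real_threshold = 1,
                                          grid = seq(0.05, 3, by = 0.05)) {
  if (!length(grid)) stop("empty calibration grid", call. = FALSE)
  rm_ <- if (inherits(real_fc, "fold_change_table")) fc_matrix(real_fc) else real_fc
  sm_ <- if (inherits(synth_fc, "fold_change_table")) fc_matrix(synth_fc) else synth_fc
  shared <- intersect(colnames(rm_), colnames(sm_))
  if (!length(shared))
    stop("no shared conditions between real and synthetic fold changes",
         call. = FALSE)
  rm_ <- abs(rm_[, shared, drop = FALSE])
  sm_ <- abs(sm_[, shared, drop = FALSE])
  target <- mean(colSums(rm_ > real_threshold))
  counts <- vapply(grid, function(t) mean(colSums(sm_ > t)), 0)
  gap <- abs(counts - target)
  best <- grid[which.min(gap)]  # which.min takes the first (smallest) tie
  attr(best, "trace") <- tibble::tibble(threshold = grid,
                                        mean_deg_count = counts, gap = gap)
  attr(best, "target_mean_count") <- target
  best
}

#' Overlap ratio of two gene (or pathway) sets
#'
#' `"reference"` divides the intersection by the reference set `b` (the
#' real-data set when scoring synthetic calls against real ones);
#' `"jaccard"` divides by the union (symmetric, used for subgroup-vs-
#' subgroup comparisons). An empty denominator is undefined and returns
#' `NA`.
#'
#' @param a,b Character vectors over the same universe; `b` is the
#'   reference under the `"reference"` convention.
#' @param convention `"reference"` or `"jaccard"`.
#' @return A scalar in \[0, 1\], or `NA_real_`.
#' @export
overlap_ratio <- function(a, b, convention = c("reference", "jaccard")) {
  convention <- match.arg(convention)
  a <- unique(a)
  b <- unique(b)
  den <- switch(convention, reference = length(b),
                jaccard = length(union(a, b)))
  if (den == 0L) return(NA_real_)
  length(intersect(a, b)) / den
}

#' Hypergeometric over-representation of gene sets
#'
#' One-sided upper-tail hypergeometric test of each gene set against the
#' query (DEG) set, both intersected with the background universe.
#' Significance uses the raw p-value at `alpha` by default; an optional
#' Benjamini-Hochberg adjustment can be switched on.
#'
#' @param query Character vector of called genes.
#' @param gene_sets Named list of gene-id vectors (see [read_gmt()]).
#' @param background Character vector: the gene universe (must contain
#'   `query`; defaults in callers to all genes in the expression matrix).
#' @param alpha Significance level (default 0.05).
#' @param adjust Apply Benjamini-Hochberg before flagging significance.
#' @return Tibble: `set`, `overlap`, `set_size`, `query_size`,
#'   `background_size`, `p_value`, (`p_adjusted`,) `significant`.
#' @export
enrich <- function(query, gene_sets, background, alpha = 0.05,
                   adjust = FALSE) {
  background <- unique(background)
  if (!length(background)) stop("empty background", call. = FALSE)
  query <- intersect(unique(query), background)
  out <- purrr::imap_dfr(gene_sets, function(members, nm) {
    set <- intersect(unique(members), background)
    k <- length(intersect(set, query))
    p <- stats::phyper(k - 1L, length(set),
                       length(background) - length(set),
                       length(query), lower.tail = FALSE)
    tibble::tibble(set = nm, overlap = k, set_size = length(set),
                   query_size = length(query),
                   background_size = length(background), p_value = p)
  })
  if (adjust) {
    out$p_adjusted <- stats::p.adjust(out$p_value, "BH")
    out$significant <- out$p_adjusted < alpha
  } else {
    out$significant <- out$p_value < alpha
  }
  out
}

#' DEG and pathway concordance between synthetic and real profiles
#'
#' Per shared treatment condition: the overlap ratio between the DEG set
#' called from synthetic fold changes (at `synth_threshold`, normally the
#' [calibrate_synthetic_threshold()] output) and the real-data DEG set
#' (at `real_threshold`). With `gene_sets`, both DEG sets additionally go
#' through [enrich()] and the significant-pathway sets are compared the
#' same way.
#'
#' @param real_fc,synth_fc Fold-change tables over matched conditions.
#' @param real_threshold,synth_threshold DEG thresholds.
#' @param gene_sets Optional named list for pathway-level concordance.
#' @param background Gene universe for [enrich()]; default all genes in
#'   `real_fc`.
#' @param convention Overlap convention (default `"reference"`: real set
#'   in the denominator). Conditions with an empty denominator yield `NA`.
#' @param alpha Pathway significance level.
#' @return Tibble: condition fields, `type` (`"deg"`/`"pathway"`),
#'   `n_real`, `n_synth`, `overlap`.
#' @export
deg_concordance <- function(real_fc, synth_fc, real_threshold = 1,
                            synth_threshold = 1, gene_sets = NULL,
                            background = NULL,
                            convention = c("reference", "jaccard"),
                            alpha = 0.05) {
  convention <- match.arg(convention)
  rdeg <- call_degs(real_fc, real_threshold)
  sdeg <- call_degs(synth_fc, synth_threshold)
  shared <- intersect(names(rdeg), names(sdeg))
  if (!length(shared)) stop("no shared conditions", call. = FALSE)
  info <- real_fc$values[!duplicated(real_fc$values$condition),
                         c("condition", "compound", "organ", "dose",
                           "time_days")]
  if (is.null(background) && !is.null(gene_sets))
    background <- unique(real_fc$values$gene)
  rows <- purrr::map_dfr(shared, function(k) {
    deg_row <- tibble::tibble(condition = k, type = "deg",
                              n_real = length(rdeg[[k]]),
                              n_synth = length(sdeg[[k]]),
                              overlap = overlap_ratio(sdeg[[k]], rdeg[[k]],
                                                      convention))
    if (is.null(gene_sets)) return(deg_row)
    rp <- enrich(rdeg[[k]], gene_sets, background, alpha)
    sp <- enrich(sdeg[[k]], gene_sets, background, alpha)
    rsets <- rp$set[rp$significant]
    ssets <- sp$set[sp$significant]
    dplyr::bind_rows(deg_row,
      tibble::tibble(condition = k, type = "pathway",
                     n_real = length(rsets), n_synth = length(ssets),
                     overlap = overlap_ratio(ssets, rsets, convention)))
  })
  dplyr::left_join(rows, info, by = "condition")
}

#' Replicate-subgroup reference experiment
#'
#' The yardstick for "how concordant can two identical experiments be":
#' replicates of each treatment group (and of its time-matched control)
#' are partitioned at random into `n_groups` subgroups of `group_size`
#' rats; each subgroup is treated as an independent experiment, DEGs are
#' called per subgroup against its subgroup-matched control, and all
#' `choose(n_groups, 2)` pairwise subgroup overlaps are reported (six
#' comparisons per treatment in the 4 x 3 design). With `gene_sets`,
#' pathway-level overlaps are added.
#'
#' @param expression Genes x samples log2 matrix.
#' @param metadata Sample metadata.
#' @param organ Organ to analyse.
#' @param group_size Rats per subgroup (default 3).
#' @param n_groups Number of subgroups (default 4).
#' @param threshold DEG threshold.
#' @param gene_sets Optional named list for pathway overlaps.
#' @param convention Overlap convention; subgroup pairs are symmetric so
#'   the default is `"jaccard"`.
#' @param alpha Pathway significance level.
#' @param seed Seed for the random partition.
#' @return Tibble: `compound`, `dose`, `time_days`, `group_a`, `group_b`,
#'   `type`, `overlap`.
#' @export
subgroup_replication <- function(expression, metadata, organ,
                                 group_size = 3L, n_groups = 4L,
                                 threshold = 1, gene_sets = NULL,
                                 convention = c("jaccard", "reference"),
                                 alpha = 0.05, seed = 1L) {
  convention <- match.arg(convention)
  meta <- dplyr::filter(metadata, .data$organ == !!organ,
                        .data$sample_id %in% colnames(expression))
  need <- group_size * n_groups
  treatments <- dplyr::filter(meta, .data$dose != "control")
  tkeys <- unique(condition_key(treatments))
  background <- rownames(expression)
  with_seed(seed, {
    per_treatment <- lapply(tkeys, function(k) {
      trt <- meta[condition_key(meta) == k, ]
      ctl <- dplyr::filter(meta, .data$compound == trt$compound[1],
                           .data$dose == "control",
                           .data$time_days == trt$time_days[1])
      if (nrow(trt) < need || nrow(ctl) < need)
        stop("treatment '", k, "' needs ", need,
             " treated and control replicates for the subgroup design",
             call. = FALSE)
      part <- function(ids) {
        ids <- sample(ids, need)
        split(ids, rep(seq_len(n_groups), each = group_size))
      }
      gtrt <- part(trt$sample_id)
      gctl <- part(ctl$sample_id)
      degs <- lapply(seq_len(n_groups), function(g) {
        fc <- rowMeans(expression[, gtrt[[g]], drop = FALSE]) -
          rowMeans(expression[, gctl[[g]], drop = FALSE])
        list(deg = background[abs(fc) > threshold])
      })
      if (!is.null(gene_sets)) {
        for (g in seq_len(n_groups)) {
          en <- enrich(degs[[g]]$deg, gene_sets, background, alpha)
          degs[[g]]$pathway <- en$set[en$significant]
        }
      }
      cmb <- utils::combn(n_groups, 2L)
      purrr::map_dfr(seq_len(ncol(cmb)), function(j) {
        a <- cmb[1L, j]
        b <- cmb[2L, j]
        base <- tibble::tibble(compound = trt$compound[1], dose = trt$dose[1],
                               time_days = trt$time_days[1],
                               group_a = a, group_b = b)
        out <- dplyr::mutate(base, type = "deg",
                             overlap = overlap_ratio(degs[[a]]$deg,
                                                     degs[[b]]$deg, convention))
        if (!is.null(gene_sets))
          out <- dplyr::bind_rows(out,
            dplyr::mutate(base, type = "pathway",
                          overlap = overlap_ratio(degs[[a]]$pathway,
                                                  degs[[b]]$pathway,
                                                  convention)))
        out
      })
    })
    dplyr::bind_rows(per_treatment)
  })
}
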