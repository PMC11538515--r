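#' Configuration of the synthetic paired-organ cohort
#'
#' The generator emulates the structure of a repeated-dose rat
#' toxicogenomics study: per compound, a grid of dose levels (with
#' time-matched controls) and treatment durations, three replicate rats
#' per condition, measured in both liver and kidney, with histopathology
#' findings attached at the condition level. One latent treatment state
#' per (compound, dose, time) drives both organs through organ-specific
#' loading matrices, which is what makes cross-organ translation
#' learnable and gives an analytic oracle ([oracle_translate()]).
#'
#' Latent magnitudes are `effect_scale * dose_factor * time_factor *
#' compound_magnitude`, monotone in dose by construction, increasing with
#' time (the "early biomarker" structure); controls have zero latent
#' state. Profiles are `baseline + W s + noise` in log2 units with
#' baselines in \[4, 12\].
#'
#' @param n_genes Number of genes.
#' @param n_compounds Number of compounds (each present in both organs).
#' @param doses Dose levels; must include `"control"`.
#' @param times Treatment durations in days.
#' @param replicates Rats per condition and organ.
#' @param latent_dim Latent dimension K of the treatment state.
#' @param noise_sd Per-gene replicate noise SD (log2 units).
#' @param effect_scale Overall latent-magnitude scale.
#' @param dose_factors Named multipliers per dose (control must be 0).
#' @param time_factors Named multipliers per time, increasing.
#' @param necrosis_threshold Latent-norm threshold above which a condition
#'   is necrosis positive.
#' @param benign_fraction Fraction of sub-threshold treated conditions
#'   given an unrelated benign finding (exercises the "excluded" status).
#' @param nonlinear Apply an elementwise tanh to the organ effect `W s`
#'   (stresses the translator beyond the linear regime; disables the
#'   oracle).
#' @param seed Master seed.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_genes = 30L, n_compounds = 6L,
                          doses = c("control", "low", "middle", "high"),
                          times = c(3, 7, 14, 28), replicates = 3L,
                          latent_dim = 3L, noise_sd = 0.3,
                          effect_scale = 2,
                          dose_factors = c(control = 0, low = 0.5,
                                           middle = 1, high = 1.5),
                          time_factors = c(`3` = 0.7, `7` = 0.85,
                                           `14` = 1, `28` = 1.2),
                          necrosis_threshold = 2,
                          benign_fraction = 0.15,
                          nonlinear = FALSE, seed = 1L) {
  stopifnot(n_genes >= 1, n_compounds >= 1, replicates >= 1,
            latent_dim >= 1, noise_sd >= 0, "control" %in% doses,
            dose_factors[["control"]] == 0,
            all(doses %in% names(dose_factors)),
            all(as.character(times) %in% names(time_factors)))
  structure(list(n_genes = as.integer(n_genes),
                 n_compounds = as.integer(n_compounds),
                 doses = doses, times = times,
                 replicates = as.integer(replicates),
                 latent_dim = as.integer(latent_dim), noise_sd = noise_sd,
                 effect_scale = effect_scale, dose_factors = dose_factors,
                 time_factors = time_factors,
                 necrosis_threshold = necrosis_threshold,
                 benign_fraction = benign_fraction,
                 nonlinear = isTRUE(nonlinear), seed = as.integer(seed)),
            class = "cohort_config")
}

#' Simulate a paired two-organ toxicogenomic cohort
#'
#' @param config A [cohort_config()].
#' @param attach_findings Attach necrosis/benign findings to the metadata
#'   via [attach_necrosis()] (default `TRUE`).
#' @return A `cohort` list: `expr_liver` and `expr_kidney` (genes x
#'   samples log2 matrices), `metadata` (both organs), and `truth`
#'   (baselines, loading matrices, per-condition latent states and
#'   necrosis labels, plus the config). Bit-identical under a fixed seed.
#' @export
simulate_cohort <- function(config = cohort_config(), attach_findings = TRUE) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(config$seed, {
    g <- config$n_genes
    K <- config$latent_dim
    genes <- sprintf("gene%03d", seq_len(g))
    compounds <- sprintf("cmpd%02d", seq_len(config$n_compounds))
    b <- list(liver = stats::runif(g, 4, 12), kidney = stats::runif(g, 4, 12))
    W <- list(liver = matrix(stats::rnorm(g * K, sd = 1 / sqrt(K)), g, K),
              kidney = matrix(stats::rnorm(g * K, sd = 1 / sqrt(K)), g, K))
    for (o in names(b)) {
      names(b[[o]]) <- genes
      rownames(W[[o]]) <- genes
    }
    u <- lapply(compounds, function(cp) {
      v <- stats::rnorm(K)
      v / sqrt(sum(v^2))
    })
    names(u) <- compounds
    mag <- stats::setNames(stats::runif(config$n_compounds, 0.7, 1.3),
                           compounds)

    grid <- tidyr::expand_grid(compound = compounds, dose = config$doses,
                               time_days = config$times)
    s_list <- purrr::pmap(grid, function(compound, dose, time_days) {
      norm <- config$effect_scale * config$dose_factors[[dose]] *
        config$time_factors[[as.character(time_days)]] * mag[[compound]]
      norm * u[[compound]]
    })
    grid$s_norm <- vapply(s_list, function(s) sqrt(sum(s^2)), 0)
    grid$necrosis <- grid$s_norm > config$necrosis_threshold
    latents <- grid
    latents$s <- s_list

    meta_rows <- list()
    expr <- list(liver = list(), kidney = list())
    for (i in seq_len(nrow(grid))) {
      s <- s_list[[i]]
      for (organ in c("liver", "kidney")) {
        eff <- as.numeric(W[[organ]] %*% s)
        if (config$nonlinear) eff <- tanh(eff)
        mu <- b[[organ]] + eff
        for (r in seq_len(config$replicates)) {
          id <- sprintf("%s_%s_%s_%gd_r%d", grid$compound[i], organ,
                        grid$dose[i], grid$time_days[i], r)
          noise <- if (config$noise_sd > 0)
            stats::rnorm(g, sd = config$noise_sd) else 0
          expr[[organ]][[id]] <- mu + noise
          meta_rows[[id]] <- tibble::tibble(
            sample_id = id, compound = grid$compound[i], organ = organ,
            dose = grid$dose[i], time_days = grid$time_days[i],
            replicate_id = sprintf("rat%d", r))
        }
      }
    }
    to_mat <- function(lst) {
      m <- do.call(cbind, lst)
      rownames(m) <- genes
      m
    }
    metadata <- dplyr::bind_rows(meta_rows)
    metadata$findings <- rep(list(character(0)), nrow(metadata))
    truth <- list(b_liver = b$liver, b_kidney = b$kidney,
                  W_liver = W$liver, W_kidney = W$kidney,
                  latents = latents, config = config)
    if (attach_findings)
      metadata <- attach_necrosis(metadata, truth)
    structure(list(expr_liver = to_mat(expr$liver),
                   expr_kidney = to_mat(expr$kidney),
                   metadata = metadata, truth = truth),
              class = "cohort")
  })
}

#' @export
print.cohort <- function(x, ...) {
  cfg <- x$truth$config
  cat("<cohort>", cfg$n_genes, "genes,", cfg$n_compounds, "compounds,",
      ncol(x$expr_liver), "profiles per organ\n")
  invisible(x)
}

#' Attach necrosis (and benign) findings to cohort metadata
#'
#' Conditions whose latent-state norm exceeds the configured threshold get
#' a `"necrosis"` finding on every replicate (in both organs); a seeded
#' random fraction of the remaining treated conditions get a benign
#' `"vacuolation"` finding on their first replicate, so the three-way
#' positive/negative/excluded labelling is exercised.
#'
#' @param metadata Cohort metadata tibble.
#' @param truth The cohort's `truth` component.
#' @param benign_fraction Overrides the config value if given.
#' @param seed Seed for the benign draw (default derived from the cohort
#'   seed).
#' @return The metadata with an updated `findings` list-column.
#' @export
attach_necrosis <- function(metadata, truth, benign_fraction = NULL,
                            seed = NULL) {
  cfg <- truth$config
  benign_fraction <- benign_fraction %||% cfg$benign_fraction
  seed <- seed %||% (cfg$seed + 1L)
  lat <- truth$latents
  tkey <- paste(lat$compound, lat$dose, lat$time_days, sep = "|")
  pos_keys <- tkey[lat$necrosis]
  sub_keys <- tkey[!lat$necrosis & lat$dose != "control"]
  benign_keys <- if (benign_fraction > 0 && length(sub_keys))
    with_seed(seed, sample(sub_keys, round(benign_fraction * length(sub_keys))))
  else character(0)
  mkey <- treatment_key(metadata)
  findings <- metadata$findings %||% rep(list(character(0)), nrow(metadata))
  first_rep <- !duplicated(paste(mkey, metadata$organ))
  for (i in seq_len(nrow(metadata))) {
    f <- findings[[i]]
    if (mkey[i] %in% pos_keys) f <- union(f, "necrosis")
    if (mkey[i] %in% benign_keys && first_rep[i]) f <- union(f, "vacuolation")
    findings[[i]] <- f
  }
  metadata$findings <- findings
  metadata
}

#' Ground-truth translation oracle
#'
#' Linear-algebra best case for any translator: estimate the latent
#' treatment state by least squares from the source profile,
#' `s_hat = argmin ||source - b_src - W_src s||`, then emit
#' `b_tgt + W_tgt s_hat`. With zero noise this reproduces the true
#' noiseless target profile exactly; with noise it gives the accuracy
#' ceiling the adversarial translator is measured against.
#'
#' @param truth A cohort's `truth` component (linear cohorts only).
#' @param source_profiles Genes x n matrix of source-organ log2 profiles.
#' @param source_organ `"liver"` or `"kidney"`.
#' @return Genes x n matrix of expected target-organ profiles.
#' @export
oracle_translate <- function(truth, source_profiles, source_organ) {
  stopifnot(source_organ %in% c("liver", "kidney"))
  if (isTRUE(truth$config$nonlinear))
    stop("the linear oracle is undefined for a nonlinear cohort",
         call. = FALSE)
  tgt <- setdiff(c("liver", "kidney"), source_organ)
  Ws <- truth[[paste0("W_", source_organ)]]
  Wt <- truth[[paste0("W_", tgt)]]
  qrW <- qr(Ws)
  if (qrW$rank < ncol(Ws))
    stop("source loading matrix is rank deficient", call. = FALSE)
  if (is.null(dim(source_profiles)))
    source_profiles <- matrix(source_profiles,
                              dimnames = list(names(source_profiles), NULL))
  resid <- source_profiles - truth[[paste0("b_", source_organ)]]
  s_hat <- qr.coef(qrW, resid)
  out <- truth[[paste0("b_", tgt)]] + Wt %*% s_hat
  dimnames(out) <- dimnames(source_profiles)
  out
}

#' Noiseless ground-truth profiles for cohort samples
#'
#' Convenience accessor: the exact `baseline + W s` profile (no replicate
#' noise) for each metadata row, used as the evaluation target for
#' translated profiles.
#'
#' @param truth A cohort's `truth` component.
#' @param meta Metadata rows (must carry `compound`, `organ`, `dose`,
#'   `time_days`).
#' @return Genes x nrow(meta) matrix, columns named by `sample_id` when
#'   present.
#' @export
true_profiles <- function(truth, meta) {
  lat <- truth$latents
  lkey <- paste(lat$compound, lat$dose, lat$time_days, sep = "|")
  mkey <- treatment_key(meta)
  idx <- match(mkey, lkey)
  if (anyNA(idx)) stop("metadata rows outside the cohort grid", call. = FALSE)
  cols <- vapply(seq_len(nrow(meta)), function(i) {
    W <- truth[[paste0("W_", meta$organ[i])]]
    eff <- as.numeric(W %*% lat$s[[idx[i]]])
    if (isTRUE(truth$config$nonlinear)) eff <- tanh(eff)
    truth[[paste0("b_", meta$organ[i])]] + eff
  }, numeric(length(truth$b_liver)))
  colnames(cols) <- meta$sample_id %||% NULL
  rownames(cols) <- names(truth$b_liver)
  cols
}

#' Write a cohort to plain-text files
#'
#' Writes `expr_liver.tsv`, `expr_kidney.tsv`, `meta.tsv` and a
#' `truth_summary.json` (latent norms and necrosis labels per condition)
#' into a directory.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_expression(cohort$expr_liver, file.path(dir, "expr_liver.tsv"))
  write_expression(cohort$expr_kidney, file.path(dir, "expr_kidney.tsv"))
  write_metadata(cohort$metadata, file.path(dir, "meta.tsv"))
  lat <- cohort$truth$latents
  jsonlite::write_json(
    list(conditions = lat[c("compound", "dose", "time_days", "s_norm",
                            "necrosis")],
         necrosis_threshold = cohort$truth$config$necrosis_threshold,
         seed = cohort$truth$config$seed),
    file.path(dir, "truth_summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
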