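# Fixtures are built in code; nothing is read from disk except files the
# tests themselves write to tempdir().

# A hand-sized metadata tibble: one compound, 2 treated liver, 3 treated
# kidney, 1 control in each organ (the worked pairing example).
pairing_fixture <- function() {
  tibble::tibble(
    sample_id = c("L1", "L2", "Lc", "K1", "K2", "K3", "Kc"),
    compound = "cmpdA",
    organ = c("liver", "liver", "liver", "kidney", "kidney", "kidney",
              "kidney"),
    dose = c("low", "high", "control", "low", "middle", "high", "control"),
    time_days = c(3, 7, 3, 3, 7, 14, 3),
    replicate_id = paste0("rat", 1:7),
    findings = rep(list(character(0)), 7)
  )
}

# Random small metadata for property tests: n_compounds compounds, random
# organ coverage, random doses/times/replicates.
random_metadata <- function(n_compounds = 3) {
  rows <- list()
  for (ci in seq_len(n_compounds)) {
    for (organ in c("liver", "kidney")) {
      n <- sample(0:4, 1)
      if (n == 0) next
      rows[[paste(ci, organ)]] <- tibble::tibble(
        compound = paste0("c", ci),
        organ = organ,
        dose = sample(c("control", "low", "middle", "high"), n, replace = TRUE),
        time_days = sample(c(3, 7, 14, 28), n, replace = TRUE)
      )
    }
  }
  meta <- dplyr::bind_rows(rows)
  if (nrow(meta) == 0) return(random_metadata(n_compounds))
  meta$sample_id <- paste0("s", seq_len(nrow(meta)))
  meta$replicate_id <- paste0("rat", seq_len(nrow(meta)))
  meta$findings <- rep(list(character(0)), nrow(meta))
  meta
}

# Small cohorts used across test files; memoised so each configuration is
# simulated once per test run.
.cohort_cache <- new.env(parent = emptyenv())

cached_cohort <- function(key = "default", ...) {
  if (is.null(.cohort_cache[[key]]))
    .cohort_cache[[key]] <- simulate_cohort(cohort_config(...))
  .cohort_cache[[key]]
}

small_cohort <- function() cached_cohort("small", times = c(3, 7), seed = 42)

# Desk-scale training configuration shared by the end-to-end tests.
desk_train_config <- function(seed = 1L, epochs = 300L) {
  transtox_config(epochs = epochs, batch_size = 128L, lambda_cycle = 10,
                  gen_hidden = c(64L, 32L), gen_dropout = 0,
                  disc_hidden = c(16L, 8L), disc_dropout = 0,
                  g_lr = 2e-3, d_lr = 0.05, noise_dim = 8L,
                  seed = seed, eval_every = 50L)
}

# Trained miniature models are expensive; train each seed at most once per
# test run and share across test files.
.model_cache <- new.env(parent = emptyenv())

cached_model <- function(seed = 1L, epochs = 300L) {
  key <- paste0("m", seed, "_", epochs)
  if (is.null(.model_cache[[key]])) {
    co <- small_cohort()
    sp <- split_by_compound(co$metadata, 0.2, seed = 1)
    pairs <- build_pairs(co$metadata, sp$train_compounds)
    expr <- cbind(co$expr_liver, co$expr_kidney)
    .model_cache[[key]] <- list(
      model = train_transtox(pairs, expr, co$metadata,
                             desk_train_config(seed, epochs)),
      split = sp)
  }
  .model_cache[[key]]
}

cluster_silhouette <- function(dist_matrix, labels) {
  sil <- cluster::silhouette(as.integer(factor(labels)),
                             dmatrix = dist_matrix)
  mean(sil[, "sil_width"])
}

mean_cosine <- function(a, b) {
  mean(vapply(seq_len(ncol(a)), function(i)
    cosine_similarity(a[, i], b[, i]), 0))
}
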