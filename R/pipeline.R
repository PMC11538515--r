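#' Default pipeline configuration
#'
#' A nested list mirroring the pipeline stages; any entry can be
#' overridden by the `config` argument of [run_pipeline()] (or a YAML file
#' with the same structure). `cohort` feeds [cohort_config()], `train`
#' feeds [transtox_config()]; the remaining sections parameterise the
#' split, translation, evaluation, DEG and classifier stages.
#'
#' @param seed Master seed; stage seeds derive from it.
#' @return Named list of stage settings.
#' @export
default_pipeline_config <- function(seed = 1L) {
  list(seed = as.integer(seed),
       cohort = list(seed = as.integer(seed)),
       split = list(test_fraction = 0.2),
       pairing = list(mode = "strict"),
       train = list(epochs = 300L, batch_size = 128L, lambda_cycle = 10,
                    gen_hidden = c(64L, 32L), gen_dropout = 0,
                    disc_hidden = c(16L, 8L), disc_dropout = 0,
                    g_lr = 2e-3, d_lr = 0.05, noise_dim = 8L,
                    seed = as.integer(seed)),
       evaluate = list(max_pairs = 1e4),
       deg = list(real_threshold = 1, grid = seq(0.05, 3, by = 0.05)),
       classify = list(finding_term = "necrosis"))
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(override[[nm]]) && is.list(base[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Run the end-to-end pipeline on a synthetic cohort
#'
#' Chains simulate, pair, train, translate, evaluate, deg and classify in
#' dependency order, writing stage outputs and a reproducibility manifest
#' (config snapshot, seeds, output inventory with MD5 digests) under
#' `out_dir`. Stages are selectable; a selected stage whose inputs were
#' not produced in this call fails with a message naming the stage to run
#' first. Determinism: the master seed fixes every stage, so re-running
#' an identical manifest reproduces the summary numbers.
#'
#' @param config List (or YAML file path) of overrides merged onto
#'   [default_pipeline_config()].
#' @param out_dir Output directory.
#' @param stages Stage subset, in any order; dependencies are checked.
#' @return The manifest (list), invisibly; also written as
#'   `manifest.json`.
#' @export
run_pipeline <- function(config = list(), out_dir = tempfile("organxlate_"),
                         stages = c("simulate", "pair", "train", "translate",
                                    "evaluate", "deg", "classify")) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  cfg <- merge_config(default_pipeline_config(config$seed %||% 1L), config)
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  state <- new.env(parent = emptyenv())
  need <- function(what, stage, produced_by) {
    if (is.null(state[[what]]))
      stop("stage '", stage, "' needs outputs of '", produced_by,
           "'; run it first", call. = FALSE)
    state[[what]]
  }
  summary <- list()

  if ("simulate" %in% stages) {
    state$cohort <- simulate_cohort(do.call(cohort_config, cfg$cohort))
    write_cohort(state$cohort, file.path(out_dir, "cohort"))
    summary$n_profiles_per_organ <- ncol(state$cohort$expr_liver)
  }

  if ("pair" %in% stages) {
    co <- need("cohort", "pair", "simulate")
    state$split <- split_by_compound(co$metadata,
                                     cfg$split$test_fraction %||% 0.2,
                                     seed = cfg$seed)
    state$expr <- cbind(co$expr_liver, co$expr_kidney)
    state$train_pairs <- build_pairs(co$metadata, state$split$train_compounds,
                                     cfg$pairing$mode)
    state$test_pairs <- build_pairs(co$metadata, state$split$test_compounds,
                                    cfg$pairing$mode)
    utils::write.table(as.data.frame(state$train_pairs),
                       file.path(out_dir, "train_pairs.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    summary$n_train_pairs <- nrow(state$train_pairs)
    summary$n_test_pairs <- nrow(state$test_pairs)
  }

  if ("train" %in% stages) {
    co <- need("cohort", "train", "simulate")
    tp <- need("train_pairs", "train", "pair")
    state$model <- train_transtox(tp, state$expr, co$metadata,
                                  do.call(transtox_config, cfg$train))
    saveRDS(state$model, file.path(out_dir, "model.rds"))
    utils::write.table(as.data.frame(state$model$loss_history),
                       file.path(out_dir, "loss_log.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    summary$final_cycle_loss <-
      state$model$loss_history$cycle[nrow(state$model$loss_history)]
  }

  if ("translate" %in% stages) {
    co <- need("cohort", "translate", "simulate")
    model <- need("model", "translate", "train")
    sp <- need("split", "translate", "pair")
    test_meta <- dplyr::filter(co$metadata,
                               .data$compound %in% sp$test_compounds)
    state$synth <- list()
    for (src in c("liver", "kidney")) {
      m <- dplyr::filter(test_meta, .data$organ == src)
      prof <- (if (src == "liver") co$expr_liver else co$expr_kidney)[, m$sample_id, drop = FALSE]
      tgt <- setdiff(c("liver", "kidney"), src)
      state$synth[[tgt]] <- translate_profiles(model, prof, m,
                                               seed = cfg$seed + 10L)
      write_expression(state$synth[[tgt]],
                       file.path(out_dir, paste0("synthetic_", tgt, ".tsv")))
    }
  }

  if ("evaluate" %in% stages) {
    co <- need("cohort", "evaluate", "simulate")
    synth <- need("synth", "evaluate", "translate")
    for (tgt in names(synth)) {
      prov <- attr(synth[[tgt]], "provenance")
      src_meta <- co$metadata[match(prov$source_sample_id,
                                    co$metadata$sample_id), ]
      # matched real profile: same compound/dose/time/rat in the target organ
      want <- paste(src_meta$compound, tgt, src_meta$dose,
                    src_meta$time_days, src_meta$replicate_id)
      have <- paste(co$metadata$compound, co$metadata$organ,
                    co$metadata$dose, co$metadata$time_days,
                    co$metadata$replicate_id)
      real_ids <- co$metadata$sample_id[match(want, have)]
      real <- (if (tgt == "liver") co$expr_liver else co$expr_kidney)[, real_ids, drop = FALSE]
      rep_ <- agreement_report(synth[[tgt]], real,
                               if (tgt == "liver") co$expr_liver else co$expr_kidney,
                               co$metadata, tgt,
                               max_pairs = cfg$evaluate$max_pairs %||% 1e4,
                               seed = cfg$seed)
      utils::write.table(as.data.frame(rep_$summary),
                         file.path(out_dir, paste0("agreement_", tgt, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      summary[[paste0("cosine_synthetic_", tgt)]] <-
        rep_$summary$synthetic_mean[rep_$summary$metric == "cosine"]
      summary[[paste0("cosine_baseline_", tgt)]] <-
        rep_$summary$baseline_mean[rep_$summary$metric == "cosine"]
      state[[paste0("agreement_", tgt)]] <- rep_
    }
  }

  if ("deg" %in% stages) {
    co <- need("cohort", "deg", "simulate")
    synth <- need("synth", "deg", "translate")
    sp <- state$split
    test_meta <- dplyr::filter(co$metadata,
                               .data$compound %in% sp$test_compounds)
    for (tgt in names(synth)) {
      real_expr <- if (tgt == "liver") co$expr_liver else co$expr_kidney
      tmeta <- dplyr::filter(test_meta, .data$organ == tgt)
      smeta <- synthetic_sample_metadata(synth[[tgt]])
      real_fc <- fold_changes(real_expr[, tmeta$sample_id, drop = FALSE], tmeta)
      synth_fc <- fold_changes(synth[[tgt]], smeta,
                               control_expression = real_expr[, tmeta$sample_id, drop = FALSE],
                               control_metadata = tmeta)
      thr <- cfg$deg$real_threshold %||% 1
      conc <- deg_concordance(real_fc, synth_fc, thr, thr)
      utils::write.table(as.data.frame(conc),
                         file.path(out_dir, paste0("deg_overlap_", tgt, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      summary[[paste0("deg_overlap_", tgt)]] <-
        mean(conc$overlap[conc$type == "deg"], na.rm = TRUE)
    }
  }

  if ("classify" %in% stages) {
    co <- need("cohort", "classify", "simulate")
    ds <- necrosis_dataset(co$expr_liver, co$metadata,
                           cfg$classify$finding_term %||% "necrosis")
    bal <- balanced_training_set(ds$labels, seed = cfg$seed)
    model <- train_necrosis_lr(ds$features[bal$condition, , drop = FALSE],
                               bal$status)
    ev <- evaluate_classifier(model, ds$features, ds$labels$status)
    jsonlite::write_json(as.list(glance(ev)),
                         file.path(out_dir, "necrosis_metrics.json"),
                         auto_unbox = TRUE, digits = NA)
    summary$necrosis_mcc <- ev$metrics$mcc
  }

  manifest <- list(config = cfg, stages = stages, summary = summary,
                   outputs = {
                     fls <- list.files(out_dir, recursive = TRUE,
                                       full.names = TRUE)
                     fls <- fls[basename(fls) != "manifest.json"]
                     stats::setNames(as.list(unname(tools::md5sum(fls))),
                                     basename(fls))
                   })
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(manifest)
}
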