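test_that("cohorts are reproducible and structurally sound", {
  c1 <- simulate_cohort(cohort_config(n_genes = 10, n_compounds = 2,
                                      times = c(3, 7), seed = 5))
  c2 <- simulate_cohort(cohort_config(n_genes = 10, n_compounds = 2,
                                      times = c(3, 7), seed = 5))
  expect_identical(c1$expr_liver, c2$expr_liver)
  expect_identical(c1$metadata, c2$metadata)
  # 2 compounds x 4 doses x 2 times x 3 rats per organ
  expect_equal(ncol(c1$expr_liver), 2 * 4 * 2 * 3)
  expect_identical(colnames(c1$expr_liver),
                   dplyr::filter(c1$metadata, organ == "liver")$sample_id)
  expect_true(all(is.finite(c1$expr_liver)))
  expect_s3_class(validate_metadata(c1$metadata), "tbl_df")
})

test_that("noiseless controls equal the organ baselines exactly", {
  co <- simulate_cohort(cohort_config(n_genes = 8, n_compounds = 1,
                                      noise_sd = 0, times = c(3, 7),
                                      seed = 9))
  ctrl <- dplyr::filter(co$metadata, dose == "control", organ == "liver")
  for (id in ctrl$sample_id)
    expect_equal(unname(co$expr_liver[, id]), unname(co$truth$b_liver))
})

test_that("latent magnitudes are dose-monotone and drive necrosis labels", {
  co <- small_cohort()
  lat <- co$truth$latents
  ord <- c(control = 0, low = 1, middle = 2, high = 3)
  by_ct <- split(lat, paste(lat$compound, lat$time_days))
  for (grp in by_ct) {
    grp <- grp[order(ord[grp$dose]), ]
    expect_true(all(diff(grp$s_norm) >= -1e-12))
  }
  expect_equal(lat$necrosis,
               lat$s_norm > co$truth$config$necrosis_threshold)
})

test_that("replicate noise has the configured spread", {
  co <- simulate_cohort(cohort_config(n_genes = 6, n_compounds = 1,
                                      doses = c("control", "high"),
                                      times = c(3, 7), replicates = 50,
                                      noise_sd = 0.3, seed = 4))
  m <- dplyr::filter(co$metadata, organ == "liver", dose == "high",
                     time_days == 3)
  sds <- apply(co$expr_liver[, m$sample_id], 1, sd)
  expect_true(all(abs(sds - 0.3) / 0.3 < 0.35))
  expect_lt(abs(mean(sds) - 0.3) / 0.3, 0.2)
})

test_that("the oracle inverts the linear map exactly at zero noise", {
  co <- simulate_cohort(cohort_config(n_genes = 12, n_compounds = 2,
                                      noise_sd = 0, times = c(3, 7),
                                      seed = 77))
  m <- dplyr::filter(co$metadata, organ == "liver")
  pred <- oracle_translate(co$truth, co$expr_liver[, m$sample_id], "liver")
  truth_k <- true_profiles(co$truth, dplyr::mutate(m, organ = "kidney"))
  expect_lt(max(abs(pred - truth_k)), 1e-8)
  # a control profile maps to the target baseline
  ctrl <- dplyr::filter(m, dose == "control")[1, ]
  expect_equal(unname(pred[, ctrl$sample_id]), unname(co$truth$b_kidney))
  # rank-deficient loading matrix is refused
  broken <- co$truth
  broken$W_liver[, 2] <- broken$W_liver[, 1]
  expect_error(oracle_translate(broken, co$expr_liver[, m$sample_id],
                                "liver"), "rank")
  # nonlinear cohorts have no linear oracle
  nl <- simulate_cohort(cohort_config(n_genes = 8, n_compounds = 1,
                                      nonlinear = TRUE, times = c(3, 7),
                                      seed = 3))
  expect_error(oracle_translate(nl$truth, nl$expr_liver[, 1:2], "liver"),
               "nonlinear")
})

test_that("necrosis findings follow the latent threshold", {
  co <- small_cohort()
  lab <- label_conditions(co$metadata)
  lat <- co$truth$latents
  lkey <- paste(lat$compound, lat$dose, lat$time_days, sep = "|")
  for (i in seq_len(nrow(lab))) {
    truth_pos <- lat$necrosis[match(
      paste(lab$compound[i], lab$dose[i], lab$time_days[i], sep = "|"),
      lkey)]
    if (truth_pos) expect_equal(lab$status[i], "positive")
    else expect_true(lab$status[i] %in% c("negative", "excluded"))
  }
  # threshold extremes
  none <- simulate_cohort(cohort_config(n_genes = 6, n_compounds = 1,
                                        necrosis_threshold = Inf,
                                        times = c(3, 7), seed = 2))
  expect_false(any(none$truth$latents$necrosis))
  all_pos <- simulate_cohort(cohort_config(n_genes = 6, n_compounds = 1,
                                           necrosis_threshold = 0,
                                           benign_fraction = 0,
                                           times = c(3, 7), seed = 2))
  lab2 <- label_conditions(all_pos$metadata)
  expect_true(all(lab2$status == "positive"))
  ctrl <- label_conditions(all_pos$metadata, include_controls = TRUE)
  expect_true(all(ctrl$status[ctrl$dose == "control"] == "negative"))
})

test_that("written cohorts parse back cleanly through the readers", {
  co <- simulate_cohort(cohort_config(n_genes = 6, n_compounds = 1,
                                      times = c(3, 7), seed = 13))
  dir <- withr::local_tempdir()
  expect_no_warning(write_cohort(co, dir))
  expect_no_warning({
    liver <- read_expression(file.path(dir, "expr_liver.tsv"))
    meta <- read_metadata(file.path(dir, "meta.tsv"))
  })
  expect_equal(liver, co$expr_liver, tolerance = 1e-12)
  expect_equal(meta$sample_id, co$metadata$sample_id)
  truth <- jsonlite::read_json(file.path(dir, "truth_summary.json"))
  expect_equal(truth$seed, 13)
})
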