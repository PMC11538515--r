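test_that("generator input width follows gene_dim + 2*label_width + noise_dim", {
  spec <- generator_spec(gene_dim = 3475)
  expect_equal(spec$input_width, 6978)
  expect_equal(generator_spec(10, noise_dim = 10)$input_width, 48)
  expect_equal(generator_spec(10, noise_dim = 0)$input_width, 38)
  expect_error(generator_spec(10, dropout_rates = c(0.5, 0.5),
                              hidden = c(8, 8)), "dropout_rates")
  # full-scale spec constructs and validates
  expect_s3_class(discriminator_spec(3475), "discriminator_spec")
})

test_that("assembled inputs keep component order and bounds", {
  prof <- c(0.1, 0.9, 0.5)
  src <- encode_label("liver", "low", 3)
  tgt <- encode_label("kidney", "low", 3)
  z <- sample_noise(3, 1, seed = 1)
  v <- assemble_generator_input(prof, src, tgt, z)
  expect_equal(ncol(v), 3 + 14 + 14 + 3)
  expect_equal(v[1, 1:3], prof)
  expect_equal(v[1, 4:17], as.numeric(src))
  expect_equal(v[1, 18:31], as.numeric(tgt))
  # zero-width noise block is legal (ablation config)
  v0 <- assemble_generator_input(prof, src, tgt, NULL)
  expect_equal(ncol(v0), 31)
  expect_error(assemble_generator_input(c(2, prof), src, tgt, z), "\\[0, 1\\]")
  expect_error(assemble_generator_input(matrix(prof, 1), matrix(src, 1),
                                        rbind(tgt, tgt), z), "target_label")
})

test_that("noise draws are seeded, bounded, and symmetric about 0.5", {
  z1 <- sample_noise(50, 20, seed = 9)
  z2 <- sample_noise(50, 20, seed = 9)
  expect_identical(z1, z2)
  expect_true(all(z1 >= 0 & z1 <= 1))
  big <- sample_noise(100, 100, seed = 1)
  expect_lt(abs(mean(big) - 0.5), 0.02)
  expect_equal(dim(sample_noise(0, 3, seed = 1)), c(3L, 0L))
})

test_that("loss components obey their algebra on an untrained model", {
  co <- small_cohort()
  sp <- split_by_compound(co$metadata, 0.2, seed = 1)
  pairs <- build_pairs(co$metadata, sp$train_compounds)
  expr <- cbind(co$expr_liver, co$expr_kidney)
  cfg <- desk_train_config(seed = 1, epochs = 1)
  mixed <- dplyr::bind_rows(
    utils::head(pairs[pairs$direction == "to_kidney", ], 30),
    utils::head(pairs[pairs$direction == "to_liver", ], 30))
  m <- train_transtox(mixed[seq(1, 60, by = 2), ], expr, co$metadata, cfg)
  batch <- mixed
  set.seed(1)
  l1 <- gan_losses(m, batch, expr, co$metadata, lambda_cycle = 10)
  expect_true(all(unlist(l1[c("d_liver_loss", "d_kidney_loss", "g_adv_loss",
                              "cycle_loss")]) >= 0))
  expect_equal(l1$total_g_loss, l1$g_adv_loss + 10 * l1$cycle_loss)
  set.seed(1)
  l0 <- gan_losses(m, batch, expr, co$metadata, lambda_cycle = 0)
  expect_equal(l0$total_g_loss, l0$g_adv_loss)
})

test_that("a miniature training run keeps books and stays finite", {
  co <- small_cohort()
  sp <- split_by_compound(co$metadata, 0.2, seed = 1)
  pairs <- build_pairs(co$metadata, sp$train_compounds)
  expr <- cbind(co$expr_liver, co$expr_kidney)
  m <- train_transtox(pairs[sample(nrow(pairs), 80), ], expr, co$metadata,
                      desk_train_config(seed = 3, epochs = 12))
  expect_equal(nrow(m$loss_history), 12)
  expect_true(all(is.finite(as.matrix(m$loss_history))))
  expect_equal(glance(m)$epochs, 12)
  expect_equal(nrow(tidy(m)), 12 * 5)
  expect_error(train_transtox(pairs[0, ], expr, co$metadata,
                              desk_train_config()), "empty")
})

test_that("translation is deterministic, shaped, and range-bounded", {
  fit <- cached_model(seed = 1)
  co <- small_cohort()
  m <- fit$model
  tmeta <- dplyr::filter(co$metadata, .data$organ == "liver")[1:4, ]
  prof <- co$expr_liver[, tmeta$sample_id]
  conds <- tibble::tibble(organ = "kidney", dose = c("low", "high"),
                          time_days = c(3, 7))
  s1 <- translate_profiles(m, prof, tmeta, conds, seed = 5)
  s2 <- translate_profiles(m, prof, tmeta, conds, seed = 5)
  expect_identical(s1, s2)
  expect_equal(dim(s1), c(nrow(prof), 4 * 2))
  # sigmoid output + clipping scaler => inside per-gene training range
  expect_true(all(s1 >= m$scaler$min - 1e-12 & s1 <= m$scaler$max + 1e-12))
  expect_equal(nrow(attr(s1, "provenance")), 8)
  # organ mismatch is refused
  expect_error(translate_profiles(m, prof, tmeta,
                                  tibble::tibble(organ = "liver",
                                                 dose = "low",
                                                 time_days = 3)),
               "opposite")
  # metadata view of a per-profile translation
  auto <- translate_profiles(m, prof, tmeta, seed = 2)
  sm <- synthetic_sample_metadata(auto)
  expect_equal(nrow(sm), 4)
  expect_true(all(sm$organ == "kidney"))
  expect_equal(sm$dose, tmeta$dose)
})

test_that("cycle-consistency improves over training on the linear cohort", {
  fit <- cached_model(seed = 1)
  hist <- fit$model$loss_history
  expect_lt(hist$cycle[nrow(hist)], hist$cycle[1])
})
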