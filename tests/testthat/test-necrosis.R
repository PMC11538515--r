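necro_meta <- function(findings_by_rat) {
  n <- length(findings_by_rat)
  tibble::tibble(
    sample_id = paste0("s", 1:n), compound = "cmpdA", organ = "liver",
    dose = "high", time_days = 3, replicate_id = paste0("rat", 1:n),
    findings = findings_by_rat)
}

test_that("condition labelling follows the three-way rule", {
  pos <- label_conditions(necro_meta(list("necrosis", character(0),
                                          character(0))))
  expect_equal(pos$status, "positive")
  neg <- label_conditions(necro_meta(list(character(0), character(0),
                                          character(0))))
  expect_equal(neg$status, "negative")
  exc <- label_conditions(necro_meta(list("vacuolation", character(0),
                                          character(0))))
  expect_equal(exc$status, "excluded")
  # matching is a case-insensitive substring
  sub <- label_conditions(necro_meta(list("Hepatocellular NECROSIS, focal",
                                          character(0), character(0))))
  expect_equal(sub$status, "positive")
  # configurable term
  fib <- label_conditions(necro_meta(list("fibrosis", character(0),
                                          character(0))), "fibrosis")
  expect_equal(fib$status, "positive")
})

test_that("balanced training sets keep all positives and a seeded negative draw", {
  labels <- tibble::tibble(condition = paste0("c", 1:20),
                           status = rep(c("positive", "negative"), c(4, 16)))
  b1 <- balanced_training_set(labels, seed = 2)
  b2 <- balanced_training_set(labels, seed = 2)
  expect_identical(b1, b2)
  expect_equal(nrow(b1), 8)
  expect_equal(sum(b1$status == "positive"), 4)
  expect_true(all(labels$condition[labels$status == "positive"] %in%
                    b1$condition))
  tiny <- tibble::tibble(condition = paste0("c", 1:4),
                         status = c("positive", "positive", "negative",
                                    "negative"))
  expect_equal(nrow(balanced_training_set(tiny, seed = 1)), 4)
  expect_error(balanced_training_set(
    tibble::tibble(condition = "c", status = "negative"), 1), "positive")
  expect_error(balanced_training_set(
    tibble::tibble(condition = c("a", "b", "c"),
                   status = c("positive", "positive", "negative")), 1),
    "fewer negatives")
})

test_that("confusion-derived metrics agree with exhaustive enumeration", {
  # brute-force oracle: direct formula evaluation over all confusion
  # matrices with total <= 30
  for (total in c(1, 7, 30)) {
    parts <- expand.grid(tp = 0:total, tn = 0:total, fp = 0:total)
    parts <- parts[rowSums(parts) <= total, ]
    parts$fn <- total - rowSums(parts)
    idx <- seq(1, nrow(parts), length.out = min(nrow(parts), 400))
    for (i in unique(round(idx))) {
      tp <- parts$tp[i]; tn <- parts$tn[i]
      fp <- parts$fp[i]; fn <- parts$fn[i]
      got <- classifier_metrics(confusion(tp, tn, fp, fn))
      den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
      mcc <- if (den == 0) 0 else (tp * tn - fp * fn) / sqrt(den)
      expect_equal(got$mcc, mcc, tolerance = 1e-12)
      expect_equal(got$accuracy, (tp + tn) / total, tolerance = 1e-12)
      if (tp + fn > 0)
        expect_equal(got$sensitivity, tp / (tp + fn), tolerance = 1e-12)
      if (tn + fp > 0)
        expect_equal(got$specificity, tn / (tn + fp), tolerance = 1e-12)
    }
  }
  perfect <- classifier_metrics(confusion(10, 10, 0, 0))
  expect_equal(unlist(perfect), c(mcc = 1, accuracy = 1, sensitivity = 1,
                                  specificity = 1))
})

test_that("confusion counts cross-tabulate predictions", {
  truth <- c("positive", "positive", "negative", "negative", "negative")
  pred <- c("positive", "negative", "negative", "positive", "negative")
  cc <- confusion_counts(truth, pred)
  expect_equal(unlist(unclass(cc)), c(tp = 1, tn = 2, fp = 1, fn = 1))
  expect_error(confusion_counts(character(0), character(0)), "empty")
})

test_that("the ridge logistic model separates a separable toy set deterministically", {
  set.seed(3)
  x <- rbind(matrix(rnorm(40, 0), 20, 2), matrix(rnorm(40, 6), 20, 2))
  colnames(x) <- c("gA", "gB")
  rownames(x) <- paste0("c", 1:40)
  y <- rep(c("negative", "positive"), each = 20)
  m1 <- train_necrosis_lr(x, y)
  m2 <- train_necrosis_lr(x, y)
  ev <- evaluate_classifier(m1, x, y)
  expect_equal(ev$metrics$accuracy, 1)
  # refitting the same data reproduces the coefficients exactly
  expect_identical(tidy(m1)$estimate, tidy(m2)$estimate)
  expect_error(train_necrosis_lr(x, rep("negative", 40)), "both classes")
})

test_that("label permutation drives test MCC toward zero", {
  set.seed(12)
  x <- matrix(rnorm(60 * 10), 60, 10,
              dimnames = list(paste0("c", 1:60), paste0("g", 1:10)))
  y <- rep(c("positive", "negative"), 30)
  mccs <- vapply(1:20, function(s) {
    set.seed(s)
    perm <- sample(y)
    m <- train_necrosis_lr(x[1:40, ], perm[1:40])
    evaluate_classifier(m, x[41:60, ], perm[41:60])$metrics$mcc
  }, 0)
  expect_lt(abs(mean(mccs)), 0.15)
})
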