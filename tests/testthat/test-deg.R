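fc_fixture <- function() {
  # 1 compound, 1 organ, 2 treated conditions + time-matched controls,
  # 3 rats each, hand-set means
  meta <- tibble::tibble(
    sample_id = paste0("s", 1:12), compound = "cmpdA", organ = "liver",
    dose = rep(c("low", "control", "high", "control"), each = 3),
    time_days = rep(c(3, 3, 7, 7), each = 3),
    replicate_id = paste0("rat", 1:12),
    findings = rep(list(character(0)), 12))
  expr <- matrix(5, 2, 12, dimnames = list(c("g1", "g2"), meta$sample_id))
  expr["g1", 1:3] <- c(4, 5, 6)     # treated mean 5
  expr["g1", 4:6] <- c(4, 4, 4)     # control mean 4 => FC 1
  expr["g2", 7:9] <- c(8, 8, 8)     # treated mean 8
  expr["g2", 10:12] <- c(5, 5, 5)   # control mean 5 => FC 3
  list(expr = expr, meta = meta)
}

test_that("fold changes are replicate-mean differences vs time-matched controls", {
  fx <- fc_fixture()
  fc <- fold_changes(fx$expr, fx$meta)
  m <- fc_matrix(fc)
  expect_equal(dim(m), c(2L, 2L))
  expect_equal(m["g1", "cmpdA|liver|low|3"], 1)   # (4+5+6)/3 - 4
  expect_equal(m["g2", "cmpdA|liver|high|7"], 3)
  expect_equal(m["g2", "cmpdA|liver|low|3"], 0)
  # treated == control => all zero
  flat <- fold_changes(matrix(5, 2, 12, dimnames = dimnames(fx$expr)),
                       fx$meta)
  expect_true(all(fc_matrix(flat) == 0))
  # missing control group: condition skipped with a warning
  no_ctrl <- dplyr::filter(fx$meta, !(dose == "control" & time_days == 7))
  expect_warning(fc2 <- fold_changes(fx$expr[, no_ctrl$sample_id], no_ctrl),
                 "skipped")
  expect_equal(ncol(fc_matrix(fc2)), 1)
})

test_that("DEG calling is strict and threshold-driven", {
  m <- matrix(c(1.2, -0.5, -1.7, 1.0), 4, 1,
              dimnames = list(paste0("g", 1:4), "t1"))
  expect_setequal(call_degs(m, 1)$t1, c("g1", "g3"))
  expect_false("g4" %in% call_degs(m, 1)$t1)  # |FC| = 1 exactly: not called
  expect_setequal(call_degs(m, 1e-9)$t1, c("g1", "g2", "g3", "g4"))
})

test_that("threshold calibration recovers scalar shrinkage of fold changes", {
  set.seed(31)
  real <- matrix(rnorm(200, sd = 1.2), 50, 4,
                 dimnames = list(paste0("g", 1:50), paste0("t", 1:4)))
  expect_equal(as.numeric(calibrate_synthetic_threshold(real, real)), 1)
  cal <- calibrate_synthetic_threshold(real, 0.5 * real)
  expect_equal(as.numeric(cal), 0.5, tolerance = 0.051)
  cal2 <- calibrate_synthetic_threshold(real, 2 * real)
  expect_equal(as.numeric(cal2), 2, tolerance = 0.11)
  trace <- attr(cal, "trace")
  expect_true(all(c("threshold", "mean_deg_count", "gap") %in% names(trace)))
  # degenerate: no real DEGs => smallest threshold reaching count 0
  none <- matrix(0.01, 50, 4, dimnames = dimnames(real))
  cal0 <- calibrate_synthetic_threshold(none, none)
  expect_equal(as.numeric(cal0), 0.05)
  expect_error(calibrate_synthetic_threshold(real, real, grid = numeric(0)),
               "grid")
})

test_that("overlap conventions behave as documented", {
  expect_equal(overlap_ratio(c("a", "b"), c("b", "c"), "reference"), 0.5)
  expect_equal(overlap_ratio(c("a", "b"), c("b", "c"), "jaccard"), 1 / 3)
  expect_equal(overlap_ratio(c("a"), c("a"), "reference"), 1)
  expect_equal(overlap_ratio(c("a"), c("b"), "jaccard"), 0)
  expect_true(is.na(overlap_ratio(c("a"), character(0), "reference")))
  # jaccard symmetric, reference generally not
  a <- c("x", "y", "z"); b <- c("y")
  expect_equal(overlap_ratio(a, b, "jaccard"), overlap_ratio(b, a, "jaccard"))
  expect_false(overlap_ratio(a, b, "reference") ==
                 overlap_ratio(b, a, "reference"))
})

test_that("hypergeometric enrichment matches the closed form", {
  bg <- paste0("g", 1:20)
  sets <- list(hit = paste0("g", 1:5), cold = paste0("g", 16:20))
  res <- enrich(paste0("g", 1:5), sets, bg)
  expect_equal(res$p_value[res$set == "hit"], 1 / choose(20, 5),
               tolerance = 1e-12)
  expect_true(res$significant[res$set == "hit"])
  # query = background saturates every set
  sat <- enrich(bg, sets, bg)
  expect_true(all(sat$p_value == 1))
  expect_equal(sat$overlap, c(5L, 5L))
  # empty query
  e <- enrich(character(0), sets, bg)
  expect_true(all(e$p_value == 1))
  expect_error(enrich("g1", sets, character(0)), "background")
  # BH adjustment flag
  adj <- enrich(paste0("g", 1:5), sets, bg, adjust = TRUE)
  expect_true("p_adjusted" %in% names(adj))
})

test_that("hypergeometric p-values match exhaustive enumeration on small universes", {
  set.seed(17)
  for (i in 1:25) {
    N <- sample(6:15, 1)
    bg <- paste0("g", 1:N)
    set_size <- sample(1:N, 1)
    q_size <- sample(1:N, 1)
    gene_set <- sample(bg, set_size)
    query <- sample(bg, q_size)
    k_obs <- length(intersect(gene_set, query))
    p_pkg <- enrich(query, list(s = gene_set), bg)$p_value
    # brute force: over all q-subsets of the universe, fraction with
    # overlap >= k_obs
    subsets <- utils::combn(N, q_size)
    in_set <- bg %in% gene_set
    overlaps <- colSums(matrix(in_set[subsets], nrow = q_size))
    p_brute <- mean(overlaps >= k_obs)
    expect_equal(p_pkg, p_brute, tolerance = 1e-10)
  }
})

test_that("synthetic-vs-real concordance reports per-condition overlaps", {
  fx <- fc_fixture()
  real_fc <- fold_changes(fx$expr, fx$meta)
  synth_fc <- fold_changes(fx$expr, fx$meta)  # perfect synthesis
  conc <- deg_concordance(real_fc, synth_fc)
  deg_rows <- conc[conc$type == "deg", ]
  # identical fold changes: overlap 1 where the real set is non-empty
  expect_true(all(deg_rows$overlap[deg_rows$n_real > 0] == 1))
  sets <- list(up = c("g1", "g2"))
  conc2 <- deg_concordance(real_fc, synth_fc, gene_sets = sets)
  expect_true("pathway" %in% conc2$type)
})

test_that("subgroup replication performs choose(n_groups, 2) comparisons", {
  # 12 treated + 12 control rats in one treatment
  meta <- tibble::tibble(
    sample_id = paste0("s", 1:24), compound = "cmpdA", organ = "liver",
    dose = rep(c("high", "control"), each = 12), time_days = 3,
    replicate_id = paste0("rat", 1:24),
    findings = rep(list(character(0)), 24))
  set.seed(2)
  expr <- matrix(rnorm(24 * 10, mean = 6), 10, 24,
                 dimnames = list(paste0("g", 1:10), meta$sample_id))
  expr[1:3, 1:12] <- expr[1:3, 1:12] + 3  # true signal in 3 genes
  res <- subgroup_replication(expr, meta, "liver", group_size = 3,
                              n_groups = 4, seed = 5)
  expect_equal(nrow(res), choose(4, 2))
  expect_true(all(res$overlap >= 0 & res$overlap <= 1))
  # identical replicates => identical subgroup DEGs => overlap 1
  flat <- expr
  flat[] <- rep(rowMeans(expr[, 1:12]), 24)
  flat[, 13:24] <- 5
  res1 <- subgroup_replication(flat, meta, "liver", seed = 5)
  expect_true(all(res1$overlap == 1))
  # n_groups = 2 gives a single comparison
  expect_equal(nrow(subgroup_replication(expr, meta, "liver",
                                         group_size = 6, n_groups = 2,
                                         seed = 5)), 1)
  expect_error(subgroup_replication(expr, meta, "liver", group_size = 7,
                                    n_groups = 4, seed = 5), "replicates")
})
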