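test_that("similarity metrics match hand arithmetic", {
  expect_equal(cosine_similarity(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(as.numeric(mape(c(1, 2, 3), c(1, 2, 3))), 0)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(rmse(c(2, 4), c(1, 5)), 1)
  expect_equal(as.numeric(mape(c(2, 4), c(1, 5))), 0.375)
  expect_error(cosine_similarity(c(0, 0), c(1, 1)), "zero-norm")
  m <- mape(c(0, 2), c(1, 1))
  expect_equal(attr(m, "n_excluded"), 1)
  expect_equal(as.numeric(m), 0.5)
})

test_that("metrics agree with direct formula evaluation on random pairs", {
  set.seed(21)
  for (i in 1:200) {
    a <- rnorm(30) + 5
    b <- rnorm(30) + 5
    expect_equal(cosine_similarity(a, b),
                 sum(a * b) / sqrt(sum(a^2) * sum(b^2)), tolerance = 1e-12)
    expect_equal(rmse(a, b), sqrt(mean((a - b)^2)), tolerance = 1e-12)
    expect_equal(as.numeric(mape(a, b)), mean(abs(a - b) / abs(a)),
                 tolerance = 1e-12)
  }
})

test_that("negative control enumerates non-duplicate within-organ pairs", {
  # 2 conditions x 3 rats: 15 total pairs, 6 within-condition, 9 eligible
  meta <- tibble::tibble(
    sample_id = paste0("s", 1:6), compound = "cmpdA", organ = "liver",
    dose = rep(c("low", "high"), each = 3), time_days = 3,
    replicate_id = paste0("rat", 1:6),
    findings = rep(list(character(0)), 6))
  expr <- matrix(rnorm(30), 5, 6,
                 dimnames = list(paste0("g", 1:5), meta$sample_id))
  nc <- negative_control_distribution(expr, meta, "liver", "cosine")
  expect_equal(nrow(nc), 9)
  key <- function(id) meta$dose[match(id, meta$sample_id)]
  expect_true(all(key(nc$sample_a) != key(nc$sample_b)))

  # identical profiles everywhere: the distribution degenerates to 1
  expr1 <- matrix(rep(1:5, 6), 5, 6,
                  dimnames = dimnames(expr))
  nc1 <- negative_control_distribution(expr1, meta, "liver", "cosine")
  expect_true(all(abs(nc1$value - 1) < 1e-12))

  # 2 conditions x 1 rat: exactly one eligible pair
  nc2 <- negative_control_distribution(expr[, c(1, 4)], meta[c(1, 4), ],
                                       "liver", "rmse")
  expect_equal(nrow(nc2), 1)

  # all duplicates: no eligible pair
  meta_dup <- dplyr::mutate(meta, dose = "low")
  expect_error(negative_control_distribution(expr, meta_dup, "liver"),
               "eligible")

  # the cap triggers a seeded subsample
  nc3 <- negative_control_distribution(expr, meta, "liver", "cosine",
                                       max_pairs = 4, seed = 2)
  nc4 <- negative_control_distribution(expr, meta, "liver", "cosine",
                                       max_pairs = 4, seed = 2)
  expect_equal(nrow(nc3), 4)
  expect_identical(nc3, nc4)
})

test_that("within- and between-organ variability follow their definitions", {
  g <- c("g1", "g2")
  tr <- c("t1")
  mk <- function(v) matrix(v, 2, 1, dimnames = list(g, tr))
  # x = 2, x' = 1 => v_in = 0.5 ; x=2, y=1, x'=1.5 => v_between = 1/3
  got <- gene_level_comparison(real_liver = mk(c(2, 2)),
                               synth_liver = mk(c(1, 1.5)),
                               real_kidney = mk(c(2, 1)),
                               synth_kidney = mk(c(2, 1)))
  vals <- got$values
  expect_equal(vals$v[vals$statistic == "in_liver" & vals$gene == "g1"], 0.5)
  expect_equal(vals$v[vals$statistic == "between_synth_liver" &
                        vals$gene == "g2"], ((2 - 1) - (1.5 - 1)) / 1.5)
  # perfect synthesis => all zero
  same <- gene_level_comparison(mk(c(2, 3)), mk(c(2, 3)),
                                mk(c(4, 5)), mk(c(4, 5)))
  expect_true(all(same$values$v == 0))
  # zero denominators are excluded and counted
  zf <- gene_level_comparison(mk(c(0, 2)), mk(c(1, 2)), mk(c(1, 1)),
                              mk(c(1, 1)))
  expect_equal(zf$n_excluded, 1)
  expect_error(gene_level_comparison(mk(c(1, 2)), mk(c(1, 2)),
                                     mk(c(1, 2)),
                                     matrix(1:2, 2, 1)), "grid")
})

test_that("duplicate variability covers replicate pairs per condition", {
  meta <- tibble::tibble(
    sample_id = paste0("s", 1:3), compound = "cmpdA", organ = "liver",
    dose = "low", time_days = 3, replicate_id = paste0("rat", 1:3),
    findings = rep(list(character(0)), 3))
  expr <- matrix(c(2, 2, 1, 2, 2, 2), 2, 3,
                 dimnames = list(c("g1", "g2"), meta$sample_id))
  dv <- duplicate_variability(expr, meta, "liver")
  # 3 replicates => choose(3,2) = 3 pairwise comparisons x 2 genes
  expect_equal(nrow(dv$values), 6)
  # pair (s1, s2): x = 2, x' = 1 at g1 => v = 0.5
  expect_true(any(abs(dv$values$v - 0.5) < 1e-12))
  # identical replicates => zeros
  expr_same <- expr
  expr_same[, "s2"] <- expr_same[, "s1"]
  expr_same[, "s3"] <- expr_same[, "s1"]
  same <- duplicate_variability(expr_same, meta, "liver")
  expect_true(all(same$values$v == 0))
  expect_error(duplicate_variability(expr[, 1, drop = FALSE], meta[1, ],
                                     "liver"), "replicates")
})

test_that("fraction_within applies a strict bound and gene restriction", {
  gv <- organxlate:::new_gene_variability(
    tibble::tibble(gene = c("g1", "g2"), condition = "t1",
                   statistic = "in_liver", v = c(0.05, 0.2)), 0L)
  expect_equal(fraction_within(gv, 0.1), 0.5)
  expect_equal(fraction_within(gv, 0), 0)
  expect_equal(fraction_within(gv, 0.1, genes = "g1"), 1)
  zeros <- organxlate:::new_gene_variability(
    tibble::tibble(gene = "g1", condition = "t", statistic = "s", v = 0), 0L)
  expect_equal(fraction_within(zeros, 0.1), 1)
})

test_that("important genes use a strict threshold over treatments", {
  fc <- matrix(c(0.5, -1.2, 1.0, 0.2, 0, 0), 3, 2, byrow = TRUE,
               dimnames = list(c("g1", "g2", "g3"), c("t1", "t2")))
  expect_equal(important_genes(fc, 1), "g1")   # |-1.2| > 1
  expect_equal(important_genes(fc, 0.15), c("g1", "g2"))  # 1.0 not > 1 at thr 1
  expect_length(important_genes(fc * 0, 1), 0)
})

test_that("2-D embedding is seeded and separates clear clusters", {
  set.seed(8)
  a <- matrix(rnorm(20 * 15), 20, 15) + 0
  b <- matrix(rnorm(20 * 15), 20, 15) + 8
  colnames(a) <- paste0("a", 1:15)
  colnames(b) <- paste0("b", 1:15)
  rownames(a) <- rownames(b) <- paste0("g", 1:20)
  emb1 <- embed_2d(list(groupA = a, groupB = b), seed = 4)
  emb2 <- embed_2d(list(groupA = a, groupB = b), seed = 4)
  expect_identical(emb1, emb2)
  expect_equal(nrow(emb1), 30)
  d <- as.matrix(dist(emb1[c("dim1", "dim2")]))
  sil <- cluster_silhouette(d, emb1$label)
  expect_gt(sil, 0.5)
  expect_error(embed_2d(a[, 1:2]), "at least 3")
})
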