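test_that("per-gene dispersion measures behave on hand-checkable input", {
  v <- matrix(c(5, 1, 5, 3), 2, dimnames = list(c("const", "vary"),
                                                c("s1", "s2")))
  m <- expression_matrix(v)
  sd10 <- per_gene_dispersion(m, measure = "sd_log10")
  expect_equal(unname(sd10["const"]), 0)
  cv <- per_gene_dispersion(m, measure = "cv_linear")
  expect_equal(unname(cv["const"]), 0)
  expect_equal(unname(cv["vary"]), sqrt(2) / 2, tolerance = 1e-12)
  # CV is invariant to rescaling
  m10 <- expression_matrix(v * 10, gene_meta = NULL)
  expect_equal(per_gene_dispersion(m10, measure = "cv_linear"), cv)
  # zero mean makes the CV undefined
  v0 <- matrix(c(0, 0, 1, 2), 2, byrow = TRUE,
               dimnames = list(c("zero", "g"), c("s1", "s2")))
  expect_true(is.na(per_gene_dispersion(expression_matrix(v0),
                                        measure = "cv_linear")["zero"]))
  expect_error(per_gene_dispersion(expression_matrix(
    matrix(1:2, 2, dimnames = list(c("a", "b"), "s1")))), ">= 2 samples")
})

test_that("comparing a set with itself gives F = 1 everywhere", {
  set.seed(21)
  a <- matrix(rexp(200), 20, dimnames = list(sprintf("g%02d", 1:20), NULL))
  r <- fluctuation_reproducibility(a, a)
  expect_true(all(r$records$f_statistic == 1))
  expect_true(all(abs(r$records$p_two_sided - 1) < 1e-12))
  expect_true(all(r$records$reproducible_flag))
  expect_equal(r$pcc_of_sds, 1)
})

test_that("F p-values match numeric integration of the F density", {
  # variances 4 vs 1, n = 13 vs 13
  p_pkg <- scbench:::f_test_p(4, 1, 12, 12)
  upper <- oracle_f_upper(4, 12, 12)
  expect_equal(p_pkg, 2 * min(upper, 1 - upper), tolerance = 1e-10)
  # a few more (f, df) combinations on both sides of 1
  for (case in list(c(0.3, 11, 7), c(2.5, 95, 47), c(1.1, 5, 40))) {
    up <- oracle_f_upper(case[1], case[2], case[3])
    expect_equal(scbench:::f_test_p(case[1], 1, case[2], case[3]),
                 2 * min(up, 1 - up), tolerance = 1e-10)
    expect_equal(scbench:::f_test_p(case[1], 1, case[2], case[3],
                                    alternative = "greater"),
                 up, tolerance = 1e-10)
  }
})

test_that("one- and two-sided F p-values satisfy p_two = 2 min(p_one, 1 - p_one)", {
  set.seed(31)
  for (i in 1:50) {
    f <- rexp(1) + 0.05
    d1 <- sample(2:30, 1); d2 <- sample(2:30, 1)
    p1 <- scbench:::f_test_p(f, 1, d1, d2, alternative = "greater")
    p2 <- scbench:::f_test_p(f, 1, d1, d2)
    expect_lt(abs(p2 - 2 * min(p1, 1 - p1)), 1e-12)
  }
})

test_that("the F test is calibrated under the equal-variance null", {
  set.seed(41)
  g <- 5000
  a <- matrix(10^rnorm(g * 12, 1, 0.3), g)
  b <- matrix(10^rnorm(g * 8, 1, 0.3), g)
  r <- fluctuation_reproducibility(a, b, pseudo_count = 0)
  frac <- mean(r$records$p_two_sided < 0.05)
  se <- sqrt(0.05 * 0.95 / g)
  expect_lt(abs(frac - 0.05), 3 * se)
  # reproducible-flag fraction is monotone in the threshold
  q <- r$records$q_bh
  expect_gte(mean(q > 0.6), mean(q > 0.9))
})

test_that("zero-variance genes are classified per the degeneracy rules", {
  a <- matrix(c(1, 1, 1, 2, 3, 4), 2, byrow = TRUE,
              dimnames = list(c("flat", "ok"), NULL))
  b <- matrix(c(1, 1, 1, 2, 2.5, 5), 2, byrow = TRUE,
              dimnames = list(c("flat", "ok"), NULL))
  r <- fluctuation_reproducibility(a, b)
  expect_true(r$records$degenerate["flat" == r$records$gene_id])
  expect_true(r$records$reproducible_flag[r$records$gene_id == "flat"])
  # variance in exactly one set: non-reproducible
  b2 <- b; b2["ok", ] <- 3
  r2 <- fluctuation_reproducibility(a, b2)
  expect_false(r2$records$reproducible_flag[r2$records$gene_id == "ok"])
})

test_that("single-cell variance exceeds pooled technical error when biology fluctuates", {
  tr <- make_truth(synth_config(n_genes = 500, n_de = 0), seed = 51)
  design <- rbind(design_grid("ES", sample_class = "single_cell", n = 96),
                  design_grid("ES", sample_class = "pooled_equivalent", n = 48))
  sim <- simulate_experiment(tr, design, seed = 51)
  ann <- sim$annotation
  s <- sim$matrix$values[1:500, ann$sample_id[ann$sample_class == "single_cell"]]
  p <- sim$matrix$values[1:500, ann$sample_id[ann$sample_class == "pooled_equivalent"]]
  fe <- fluctuation_vs_error(s, p)
  strong <- tr$gene_table$sigma_bio >= 0.4
  expect_lt(median(fe$records$p_one_sided[strong]), 0.001)
  # identical data: p = 0.5 per gene (F = 1)
  same <- fluctuation_vs_error(s, s)
  expect_true(all(abs(same$records$p_one_sided - 0.5) < 1e-12))
})

test_that("stronger biological fluctuation drives the one-sided p down", {
  meds <- vapply(c(0.1, 0.3, 0.6), function(sb) {
    tr <- make_truth(synth_config(n_genes = 200, n_de = 0,
                                  sigma_bio_range = c(sb, sb)), seed = 61)
    design <- rbind(design_grid("ES", sample_class = "single_cell", n = 24),
                    design_grid("ES", sample_class = "pooled_equivalent", n = 24))
    sim <- simulate_experiment(tr, design, seed = 61)
    ann <- sim$annotation
    s <- sim$matrix$values[1:200, ann$sample_class == "single_cell"]
    p <- sim$matrix$values[1:200, ann$sample_class == "pooled_equivalent"]
    median(fluctuation_vs_error(s, p)$records$p_one_sided)
  }, numeric(1))
  expect_true(all(diff(meds) < 0))
})

test_that("CV concordance behaves on identities and shared-truth platforms", {
  expect_equal(cv_concordance(c(0.1, 0.5, 0.9), c(0.1, 0.5, 0.9)), 1)
  expect_equal(cv_concordance(c(1, 2, 3), c(3, 2, 1)), -1)
  expect_error(cv_concordance(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  # two platforms measuring the same per-gene fluctuation agree when the
  # biological CV spread dominates the technical noise; many cells and a
  # moderate lognormal tail keep the per-gene CV estimator itself precise
  tr <- make_truth(synth_config(n_genes = 300, n_de = 0,
                                sigma_bio_range = c(0.05, 0.4),
                                sigma_tech = 0.05), seed = 71)
  s1 <- simulate_experiment(tr, design_grid("ES", n = 200), seed = 72,
                            dropout = FALSE)
  s2 <- simulate_experiment(tr, design_grid("ES", n = 200), seed = 73,
                            dropout = FALSE)
  cv1 <- per_gene_dispersion(s1$matrix, measure = "cv_linear")[1:300]
  cv2 <- per_gene_dispersion(s2$matrix, measure = "cv_linear")[1:300]
  expect_gt(cv_concordance(cv1, cv2), 0.9)
})
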