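test_that("log-scale PCC matches hand computations and identities", {
  a <- c(1, 10, 100, 7, 42)
  id <- log_pcc(a, a, pseudo_count = 0)
  expect_equal(id$pcc, 1)
  expect_equal(id$slope, 1)
  expect_equal(id$intercept, 0)
  # b = 10 a: correlation 1, unit slope, intercept 1 on the log scale
  aff <- log_pcc(a, 10 * a, pseudo_count = 0)
  expect_equal(aff$pcc, 1)
  expect_equal(aff$intercept, 1)
  # log pairs x = (0,1,2), y = (0,2,3): r = 1.5 / sqrt(7/3)
  h <- log_pcc(c(1, 10, 100), c(1, 100, 1000), pseudo_count = 0)
  expect_equal(h$pcc, 1.5 / sqrt(7 / 3), tolerance = 1e-12)
  expect_equal(h$pcc, 0.98198, tolerance = 1e-5)
  expect_error(log_pcc(c(1, 1, 1), c(1, 2, 3), pseudo_count = 0), "zero variance")
  expect_error(log_pcc(1:3, 1:4), "equal length")
})

test_that("detected/reproducible counting follows the threshold rules", {
  a <- c(2, 2, 0.5, 10)
  b <- c(3, 5, 3, 10)
  r <- count_reproducible(a, b, min_expr = 1, fold_threshold = 2)
  expect_equal(r$n_detected, 3L)
  expect_equal(r$n_reproducible, 2L)
  expect_equal(r$fraction_reproducible, 2 / 3)
  # identical profiles above threshold: everything reproducible
  same <- count_reproducible(c(2, 3, 4), c(2, 3, 4))
  expect_equal(same$fraction_reproducible, 1)
  # nothing detected: zero counts, fraction defined as 0
  lo <- count_reproducible(c(0.1, 0.5, 0.9), c(0.2, 0.3, 0.4))
  expect_equal(lo$n_detected, 0L)
  expect_equal(lo$fraction_reproducible, 0)
  expect_error(count_reproducible(a, b, fold_threshold = 1), "> 1")
  # strict inequalities at both boundaries
  edge <- count_reproducible(c(1, 2), c(1, 4), min_expr = 1, fold_threshold = 2)
  expect_equal(edge$n_detected, 1L)   # 1 is not > 1
  expect_equal(edge$n_reproducible, 0L)  # ratio 2 is not < 2
})

test_that("RMA log2 values are exponentiated before the fold-change rule", {
  # 8 vs 9 on log2 scale = 2-fold on linear scale, not reproducible (strict)
  r <- count_reproducible(c(8, 8), c(9, 8.5), min_expr = 7,
                          fold_threshold = 2, unit = "RMA_log2")
  expect_equal(r$n_detected, 2L)
  expect_equal(r$n_reproducible, 1L)
})

test_that("quantile normalization equalizes distributions and is idempotent", {
  v <- matrix(c(1, 5, 3, 7), 2, dimnames = list(c("g1", "g2"), c("s1", "s2")))
  qn <- quantile_normalize(expression_matrix(v))
  expect_equal(unname(qn$values), matrix(c(2, 6, 2, 6), 2))
  m <- rand_matrix(200, 6, seed = 8)
  q1 <- quantile_normalize(m)
  # all sample distributions identical
  sorted <- apply(q1$values, 2, sort)
  expect_true(all(abs(sorted - sorted[, 1]) < 1e-12))
  # sorted columns equal the mean of the input order statistics
  expect_equal(sorted[, 1], rowMeans(apply(m$values, 2, sort)))
  # idempotent; identical columns pass through unchanged
  expect_equal(quantile_normalize(q1)$values, q1$values, tolerance = 1e-12)
  same <- expression_matrix(matrix(c(1, 2, 1, 2), 2,
                                   dimnames = list(c("a", "b"), c("x", "y"))))
  expect_equal(quantile_normalize(same)$values, same$values)
  # within-sample ranks preserved
  expect_identical(apply(q1$values, 2, rank), apply(m$values, 2, rank))
})

test_that("downsampling reproduces counts at full depth and detects the only gene", {
  counts <- c(g1 = 0L, g2 = 25L, g3 = 0L)
  one <- downsample_detection(counts, depths = c(1, 5, 25), seed = 1)
  expect_true(all(one$n_detected == 1L))
  full <- downsample_detection(c(a = 10L, b = 5L, c = 85L), depths = 100,
                               mode = "exact", seed = 1)
  expect_equal(full$n_detected, 3L)
  expect_equal(full$pcc_vs_full, 1)
  expect_error(downsample_detection(counts, depths = 26), "exceeds total")
})

test_that("expected detected genes match the inclusion-probability closed form", {
  counts <- c(a = 900L, b = 90L, c = 10L)
  p <- counts / sum(counts)
  exact <- 3 - sum((1 - p)^10)
  draws <- vapply(1:10000, function(i)
    downsample_detection(counts, 10, seed = i)$n_detected, numeric(1))
  # Monte-Carlo tolerance: 4 SEs of the empirical mean
  se <- stats::sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - exact), 4 * se + 1e-9)
})

test_that("detection curve rises with depth and converges to the full profile", {
  set.seed(10)
  counts <- rpois(500, exp(runif(500, 0, 6)))
  names(counts) <- sprintf("g%03d", 1:500)
  total <- sum(counts)
  curve <- downsample_detection(counts, round(total * c(0.001, 0.01, 0.1, 1)),
                                seed = 2)
  expect_true(all(diff(curve$n_detected) >= 0))
  # correlation with the full profile improves with depth
  expect_gt(curve$pcc_vs_full[4], curve$pcc_vs_full[1])
  expect_gt(curve$pcc_vs_full[4], 0.95)
  # without-replacement sampling at full depth is the identity
  exact <- downsample_detection(counts, total, mode = "exact", seed = 2)
  expect_equal(exact$pcc_vs_full, 1)
  expect_equal(exact$n_detected, sum(counts >= 1))
})
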