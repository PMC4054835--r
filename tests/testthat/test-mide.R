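test_that("Freedman-Diaconis binning matches the hand-derived cases", {
  bs <- fd_binspec(1:8)   # IQR 3.5, width 2*3.5*8^(-1/3) = 3.5, range 7 -> K 2
  expect_equal(bs$K, 2L)
  expect_equal(bs$bin_edges, c(1, 4.5, 8))
  # zero range: single bin containing the points
  one <- fd_binspec(rep(5, 10))
  expect_equal(one$K, 1L)
  expect_true(one$bin_edges[1] <= 5 && one$bin_edges[2] >= 5)
  # zero IQR, nonzero range: ceil(log2 n) + 1 equal-width bins
  v <- c(rep(1, 20), 9)
  fb <- fd_binspec(v)
  expect_equal(fb$K, ceiling(log2(21)) + 1)
  expect_equal(diff(fb$bin_edges), rep(diff(range(v)) / fb$K, fb$K))
  expect_error(fd_binspec(1), "at least 2")
  # bin-count cap
  expect_lte(fd_binspec(c(1:20, 1e6))$K, 16L)
})

test_that("contingency tables count states into half-open bins", {
  bs <- list(bin_edges = c(0, 5, 10), K = 2L)
  tab <- contingency(c(0, 0, 10, 10), c("A", "A", "B", "B"), bs)
  expect_equal(unname(tab$counts), matrix(c(2L, 0L, 0L, 2L), 2))
  expect_equal(tab$n, 4L)
  # last bin closed: the max lands in bin K, not outside
  tab2 <- contingency(c(0, 5, 10), rep("A", 3), bs)
  expect_equal(unname(tab2$counts[, 1]), c(1L, 2L))
  expect_equal(sum(tab2$counts), tab2$n)
  expect_error(contingency(c(0, 11), c("A", "B"), bs), "outside")
})

test_that("James-Stein shrinkage reproduces the worked examples", {
  s1 <- js_shrink(ct(matrix(c(3, 1), 1)))
  expect_equal(s1$lambda_star, 1)
  expect_equal(as.vector(s1$probabilities), c(0.5, 0.5))
  s2 <- js_shrink(ct(matrix(c(8, 2), 1)))
  expect_equal(s2$lambda_star, 0.32 / 1.62, tolerance = 1e-12)
  expect_equal(as.vector(s2$probabilities), c(0.74074074, 0.25925926),
               tolerance = 1e-7)
  # counts already at the uniform target shrink to themselves
  su <- js_shrink(ct(matrix(c(5, 5, 5, 5), 2)))
  expect_equal(as.vector(su$probabilities), rep(0.25, 4))
  expect_error(js_shrink(ct(matrix(0, 1))), "empty")
})

test_that("shrunk frequencies agree with an independent oracle on random tables", {
  set.seed(101)
  for (i in 1:1000) {
    k <- sample(2:12, 1)
    counts <- as.numeric(rmultinom(1, sample(5:200, 1),
                                   rexp(k) + 0.05))
    s <- js_shrink(ct(matrix(counts, 1)))
    o <- oracle_js(counts)
    expect_equal(s$lambda_star, o$lambda, tolerance = 1e-12)
    expect_equal(as.vector(s$probabilities), o$p, tolerance = 1e-12)
    expect_equal(sum(s$probabilities), 1, tolerance = 1e-12)
    expect_true(s$lambda_star >= 0 && s$lambda_star <= 1)
  }
})

test_that("entropy matches direct evaluation and respects its bounds", {
  expect_equal(entropy_bits(c(0.5, 0.5)), 1)
  expect_equal(entropy_bits(c(1, 0)), 0)
  expect_equal(entropy_bits(c(0.75, 0.25)),
               -(0.75 * log2(0.75) + 0.25 * log2(0.25)))
  expect_equal(entropy_bits(c(0.75, 0.25)), 0.81128, tolerance = 1e-5)
  expect_error(entropy_bits(c(-0.1, 1.1)), "nonnegative")
  set.seed(7)
  for (i in 1:50) {
    p <- rexp(sample(2:10, 1)); p <- p / sum(p)
    h <- entropy_bits(p)
    expect_gte(h, 0)
    expect_lte(h, log2(length(p)) + 1e-12)
    expect_equal(h, oracle_entropy(p), tolerance = 1e-12)
  }
})

test_that("mutual information reproduces the worked tables", {
  diag2 <- mutual_information(ct(matrix(c(5, 0, 0, 5), 2)), shrink = FALSE)
  expect_equal(diag2$mi_bits, 1)
  indep <- mutual_information(ct(matrix(c(4, 4, 4, 4), 2)), shrink = FALSE)
  expect_equal(indep$mi_bits, 0)
  indep_sh <- mutual_information(ct(matrix(c(4, 4, 4, 4), 2)), shrink = TRUE)
  expect_equal(indep_sh$mi_bits, 0)
  m <- mutual_information(ct(matrix(c(4, 1, 1, 4), 2)), shrink = FALSE)
  expect_equal(m$mi_bits, 2 + 2 * (0.4 * log2(0.4) + 0.1 * log2(0.1)),
               tolerance = 1e-12)
  expect_equal(m$mi_bits, 0.27807, tolerance = 1e-5)
  # single-cell table is degenerate with zero MI
  d <- mutual_information(ct(matrix(6, 1)))
  expect_true(d$degenerate)
  expect_equal(d$mi_bits, 0)
})

test_that("MI laws hold on random tables: nonnegative, symmetric, bounded", {
  set.seed(202)
  for (i in 1:300) {
    k <- sample(2:6, 1); l <- sample(2:4, 1)
    counts <- matrix(rpois(k * l, 3) + (i %% 2), k)
    if (sum(counts) < 2) next
    for (shrink in c(TRUE, FALSE)) {
      m <- mutual_information(ct(counts), shrink = shrink)
      mt <- mutual_information(ct(t(counts)), shrink = shrink)
      expect_gte(m$mi_bits, 0)
      expect_lt(abs(m$mi_bits - mt$mi_bits), 1e-12)
      expect_lte(m$mi_bits, min(m$H_x, m$H_y) + 1e-12)
    }
  }
  # outer-product (independent) tables have zero plug-in MI; the uniform
  # table keeps MI 0 under any amount of shrinkage toward itself
  outer_tab <- outer(c(2, 6, 2), c(3, 9)) # rank-1 counts
  expect_lt(mutual_information(ct(outer_tab), shrink = FALSE)$mi_bits, 1e-12)
})

test_that("shrunk and maximum-likelihood MI converge as n grows", {
  props <- matrix(c(0.3, 0.1, 0.2, 0.4), 2)
  big <- ct(props * 1e4)
  m_sh <- mutual_information(big, shrink = TRUE)
  m_ml <- mutual_information(big, shrink = FALSE)
  expect_lt(abs(m_sh$mi_bits - m_ml$mi_bits), 0.01)
})

test_that("shrinkage reduces small-sample MSE of cell frequencies", {
  set.seed(303)
  p_true <- c(0.30, 0.20, 0.15, 0.12, 0.10, 0.07, 0.04, 0.02)
  mse_sh <- mse_ml <- numeric(2000)
  for (r in 1:2000) {
    counts <- as.numeric(rmultinom(1, 10, p_true))
    theta <- counts / 10
    sh <- as.vector(js_shrink(ct(matrix(counts, 1)))$probabilities)
    mse_ml[r] <- mean((theta - p_true)^2)
    mse_sh[r] <- mean((sh - p_true)^2)
  }
  expect_lt(mean(mse_sh), mean(mse_ml))
})

test_that("Wilcoxon rank-sum p-values match exact enumeration", {
  expect_equal(wilcoxon_rank(1:3, 4:6), 0.1)  # 2/20, all C(6,3) assignments
  expect_equal(wilcoxon_rank(c(2, 5, 9), c(2, 5, 9)), 1)
  # exact and normal-approximation modes agree for n = 12 vs 12
  set.seed(404)
  for (i in 1:20) {
    a <- rnorm(12); b <- rnorm(12, mean = runif(1, 0, 1.5))
    p_exact <- wilcoxon_rank(a, b)
    p_norm <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE,
                                                  correct = TRUE)$p.value)
    expect_lt(abs(p_exact - p_norm), 0.02)
  }
  expect_error(wilcoxon_rank(numeric(0), 1), "non-empty")
})

test_that("the DE scan ranks planted genes highly and skips constant genes", {
  tr <- make_truth(synth_config(n_genes = 400, n_de = 40), seed = 11)
  sim <- simulate_experiment(tr, design_grid(c("ES", "PrE"), n = 12), seed = 11)
  # plant an all-zero gene
  v <- sim$matrix$values
  v["gene00001", ] <- 0
  mat <- expression_matrix(v, unit = "FPKM")
  de <- de_scan(mat, sim$annotation, c("ES", "PrE"))
  expect_false(de$tested[de$gene_id == "gene00001"])
  expect_true(is.na(de$mi_bits[de$gene_id == "gene00001"]))
  gt <- tr$gene_table[-1, ]
  sub <- de[match(gt$id, de$gene_id), ]
  strong <- (!gt$de_flag) | abs(gt$log2_fold_change) >= 2
  expect_gt(auroc(sub$mi_bits[strong], gt$de_flag[strong]), 0.9)
  # q >= p under Benjamini-Hochberg
  ok <- de$tested
  expect_true(all(de$q_value[ok] >= de$p_value[ok] - 1e-12))
  expect_error(de_scan(mat, sim$annotation, c("ES", "nope")), "absent")
})
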