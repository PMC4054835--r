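# Gene-expression fluctuation analysis: per-gene dispersion (log-scale SD or
# linear-scale CV), reproducibility of fluctuations across two independent
# single-cell sets (variance-ratio F-test with Benjamini-Hochberg FDR — genes
# whose adjusted p EXCEEDS the threshold show statistically indistinguishable
# dispersion in both sets and are called reproducibly fluctuating), and the
# separation of biological fluctuation from technical error by contrasting
# single cells against pooled-equivalent samples.

#' Per-gene dispersion for a sample group
#'
#' `sd_log10`: sample SD (n-1 denominator) of `log10(value + pseudo_count)`.
#' `cv_linear`: sample SD / mean on the linear scale; NA when the mean is 0.
#'
#' @param mat An [expression_matrix()].
#' @param annotation A [sample_annotation()].
#' @param group Logical/integer/character selector of samples (passed to
#'   column indexing), or a function of the annotation returning one;
#'   must select >= 2 samples.
#' @param measure `"sd_log10"` or `"cv_linear"`.
#' @param pseudo_count Pseudo-count for the log scale.
#' @return Named numeric vector, one value per gene.
#' @export
per_gene_dispersion <- function(mat, annotation = NULL, group = NULL,
                                measure = c("sd_log10", "cv_linear"),
                                pseudo_count = 1) {
  measure <- match.arg(measure)
  vals <- mat$values
  if (!is.null(group)) {
    if (is.function(group)) group <- group(annotation)
    if (is.character(group)) group <- match(group, sample_ids(mat))
    vals <- vals[, group, drop = FALSE]
  }
  if (ncol(vals) < 2L) stop("group must contain >= 2 samples")
  if (measure == "sd_log10") {
    apply(log10(vals + pseudo_count), 1, stats::sd)
  } else {
    m <- rowMeans(vals)
    s <- apply(vals, 1, stats::sd)
    ifelse(m == 0, NA_real_, s / m)
  }
}

# two-sided variance-ratio p from the F distribution; one-sided is the
# upper tail of var_a / var_b
f_test_p <- function(var_a, var_b, df_a, df_b, alternative = "two.sided") {
  f <- var_a / var_b
  if (alternative == "greater")
    return(stats::pf(f, df_a, df_b, lower.tail = FALSE))
  lo <- stats::pf(f, df_a, df_b)
  up <- stats::pf(f, df_a, df_b, lower.tail = FALSE)
  pmin(1, 2 * pmin(lo, up))
}

#' Reproducibility of expression fluctuations across two independent sets
#'
#' Per gene, the variance ratio `F = var_a / var_b` of log-scale expression
#' is tested against the F distribution with `(n_a - 1, n_b - 1)` degrees of
#' freedom (two-sided p = `2 * min(P(F <= f), P(F >= f))`); p-values are
#' Benjamini-Hochberg adjusted across genes and a gene is flagged
#' reproducibly fluctuating when its adjusted p exceeds `q_threshold`
#' (failure to reject variance equality). Genes with zero variance in both
#' sets are degenerate-reproducible (identical dispersion); in exactly one
#' set, non-reproducible.
#'
#' @param set_a,set_b Numeric matrices (genes x samples, same genes, >= 2
#'   samples each) of expression values from two independent single-cell
#'   sets, or [expression_matrix()] objects.
#' @param q_threshold Adjusted-p threshold (default 0.6).
#' @param pseudo_count Pseudo-count for the log10 transform.
#' @return List with `pcc_of_sds` (Pearson correlation of the two per-gene SD
#'   vectors) and `records`, a data.frame per gene: `gene_id`, `sd_set_a`,
#'   `sd_set_b`, `f_statistic`, `p_two_sided`, `q_bh`, `reproducible_flag`,
#'   `degenerate`.
#' @export
fluctuation_reproducibility <- function(set_a, set_b, q_threshold = 0.6,
                                        pseudo_count = 1) {
  if (inherits(set_a, "ExpressionMatrix")) set_a <- set_a$values
  if (inherits(set_b, "ExpressionMatrix")) set_b <- set_b$values
  if (nrow(set_a) != nrow(set_b)) stop("sets must share the gene list")
  if (ncol(set_a) < 2L || ncol(set_b) < 2L) stop("need >= 2 samples per set")
  la <- log10(set_a + pseudo_count)
  lb <- log10(set_b + pseudo_count)
  sd_a <- apply(la, 1, stats::sd)
  sd_b <- apply(lb, 1, stats::sd)
  df_a <- ncol(set_a) - 1L
  df_b <- ncol(set_b) - 1L
  both_zero <- sd_a == 0 & sd_b == 0
  one_zero <- xor(sd_a == 0, sd_b == 0)
  f <- (sd_a^2) / (sd_b^2)
  p <- f_test_p(sd_a^2, sd_b^2, df_a, df_b)
  p[both_zero] <- NA_real_
  p[one_zero] <- 0           # dispersion present in exactly one set
  q <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  q[ok] <- stats::p.adjust(p[ok], method = "BH")
  flag <- !is.na(q) & q > q_threshold
  flag[both_zero] <- TRUE    # identical (zero) dispersion in both sets
  records <- data.frame(
    gene_id = if (!is.null(rownames(set_a))) rownames(set_a)
              else paste0("gene", seq_along(sd_a)),
    sd_set_a = sd_a, sd_set_b = sd_b, f_statistic = f,
    p_two_sided = p, q_bh = q, reproducible_flag = flag,
    degenerate = both_zero, stringsAsFactors = FALSE, row.names = NULL)
  pcc <- if (stats::sd(sd_a) == 0 || stats::sd(sd_b) == 0) NA_real_
         else stats::cor(sd_a, sd_b)
  list(pcc_of_sds = pcc, records = records,
       params = list(q_threshold = q_threshold, pseudo_count = pseudo_count))
}

#' Biological fluctuation vs technical error
#'
#' One-sided per-gene F-test of `var(single cells) > var(pooled-equivalent
#' samples)` on the log scale. Pooled-equivalent samples (single-cell-sized
#' aliquots of a many-cell lysate) carry measurement error only, so a small
#' p indicates fluctuation beyond technical noise.
#'
#' @param single_cells,pooled Genes x samples matrices (or
#'   [expression_matrix()]) over the same genes, >= 2 samples each.
#' @param alpha Significance level for the post-adjustment summary count.
#' @param pseudo_count Pseudo-count for the log10 transform.
#' @return List with `records` (per gene: `gene_id`, `sd_single`, `sd_pooled`,
#'   `f_statistic`, `p_one_sided`, `q_bh`) and `n_significant` at `alpha`
#'   after Benjamini-Hochberg.
#' @export
fluctuation_vs_error <- function(single_cells, pooled, alpha = 0.05,
                                 pseudo_count = 1) {
  if (inherits(single_cells, "ExpressionMatrix")) single_cells <- single_cells$values
  if (inherits(pooled, "ExpressionMatrix")) pooled <- pooled$values
  if (nrow(single_cells) != nrow(pooled)) stop("matrices must share the gene list")
  if (ncol(single_cells) < 2L || ncol(pooled) < 2L)
    stop("need >= 2 samples per group")
  ls <- log10(single_cells + pseudo_count)
  lp <- log10(pooled + pseudo_count)
  sd_s <- apply(ls, 1, stats::sd)
  sd_p <- apply(lp, 1, stats::sd)
  both_zero <- sd_s == 0 & sd_p == 0
  f <- (sd_s^2) / (sd_p^2)
  p <- f_test_p(sd_s^2, sd_p^2, ncol(single_cells) - 1L, ncol(pooled) - 1L,
                alternative = "greater")
  p[both_zero] <- NA_real_
  p[sd_p == 0 & sd_s > 0] <- 0
  q <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  q[ok] <- stats::p.adjust(p[ok], method = "BH")
  records <- data.frame(
    gene_id = if (!is.null(rownames(single_cells))) rownames(single_cells)
              else paste0("gene", seq_along(sd_s)),
    sd_single = sd_s, sd_pooled = sd_p, f_statistic = f,
    p_one_sided = p, q_bh = q, stringsAsFactors = FALSE, row.names = NULL)
  list(records = records, n_significant = sum(q <= alpha, na.rm = TRUE),
       alpha = alpha)
}

#' Cross-platform concordance of coefficients of variation
#'
#' Pearson correlation between two per-gene CV vectors measured on different
#' platforms (e.g. sequencing vs qPCR); CV is scale-free, so the comparison
#' needs no cross-platform calibration.
#'
#' @param cv_platform_1,cv_platform_2 Per-gene CV vectors over the same
#'   genes, length >= 3; NA pairs are dropped.
#' @return Pearson correlation coefficient.
#' @export
cv_concordance <- function(cv_platform_1, cv_platform_2) {
  if (length(cv_platform_1) != length(cv_platform_2))
    stop("CV vectors must share the gene list")
  keep <- !is.na(cv_platform_1) & !is.na(cv_platform_2)
  x <- cv_platform_1[keep]; y <- cv_platform_2[keep]
  if (length(x) < 3L) stop("need >= 3 genes with defined CVs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined: zero variance in a CV vector")
  stats::cor(x, y)
}
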