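# Reproducibility and sensitivity metrics between expression profiles:
# Pearson correlation on log-transformed values, the detected/reproducible
# transcript-counting rule (detection threshold + fold-change window),
# quantile normalization, and detection-vs-depth downsampling curves.

#' Pearson correlation of two log-transformed profiles
#'
#' Computes the Pearson correlation coefficient and the least-squares
#' regression line of `log10(b + pseudo_count)` on `log10(a + pseudo_count)`
#' over all genes — the standard scatter-plot summary for technical
#' replicates.
#'
#' @param profile_a,profile_b Nonnegative expression vectors of equal length
#'   (>= 3).
#' @param pseudo_count Added before the log to keep zeros finite. Default 1.
#' @return List with `pcc`, `slope`, `intercept`.
#' @export
log_pcc <- function(profile_a, profile_b, pseudo_count = 1) {
  if (length(profile_a) != length(profile_b))
    stop("profiles must have equal length")
  if (length(profile_a) < 3L) stop("need at least 3 genes")
  if (any(profile_a < 0) || any(profile_b < 0))
    stop("expression values must be nonnegative")
  x <- log10(profile_a + pseudo_count)
  y <- log10(profile_b + pseudo_count)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined: zero variance after log transform")
  slope <- stats::cov(x, y) / stats::var(x)
  list(pcc = stats::cor(x, y),
       slope = slope,
       intercept = mean(y) - slope * mean(x))
}

#' Count detected and reproducible transcripts between two profiles
#'
#' A transcript is *detected* when it is strictly above `min_expr` in both
#' profiles, and *reproducible* when, in addition, the ratio of the larger to
#' the smaller value (linear scale; log2 units are exponentiated first) is
#' strictly below `fold_threshold`. Presets for the detection threshold by
#' unit: FPKM > 1.0, tpm > 1.0, RMA (log2) > 7.0.
#'
#' @param profile_a,profile_b Expression vectors over the same genes.
#' @param min_expr Detection threshold on the declared unit scale.
#' @param fold_threshold Fold-change window (> 1), default 2.
#' @param unit Unit scale; `"RMA_log2"` values are exponentiated (base 2)
#'   before the ratio.
#' @return List of class `ReproReport`: `n_detected`, `n_reproducible`,
#'   `fraction_reproducible`, `pcc`, `slope`, `intercept`, `params`. The
#'   correlation fields are NA when fewer than 3 genes are supplied or a
#'   log-profile is constant.
#' @export
count_reproducible <- function(profile_a, profile_b, min_expr = 1,
                               fold_threshold = 2, unit = "FPKM",
                               pseudo_count = 1) {
  if (fold_threshold <= 1) stop("fold_threshold must be > 1")
  if (length(profile_a) != length(profile_b))
    stop("profiles must have equal length")
  detected <- profile_a > min_expr & profile_b > min_expr
  a <- profile_a; b <- profile_b
  if (unit == "RMA_log2") { a <- 2^a; b <- 2^b }
  ratio <- pmax(a, b) / pmin(a, b)
  repro <- detected & ratio < fold_threshold
  n_det <- sum(detected)
  fit <- if (length(profile_a) >= 3L &&
             stats::sd(log10(profile_a + pseudo_count)) > 0 &&
             stats::sd(log10(profile_b + pseudo_count)) > 0)
    log_pcc(profile_a, profile_b, pseudo_count)
  else list(pcc = NA_real_, slope = NA_real_, intercept = NA_real_)
  structure(list(n_detected = n_det,
                 n_reproducible = sum(repro),
                 fraction_reproducible = if (n_det == 0) 0 else sum(repro) / n_det,
                 pcc = fit$pcc, slope = fit$slope, intercept = fit$intercept,
                 params = list(min_expr = min_expr,
                               fold_threshold = fold_threshold,
                               pseudo_count = pseudo_count, unit = unit)),
            class = "ReproReport")
}

#' @export
print.ReproReport <- function(x, ...) {
  cat(sprintf("ReproReport: %d/%d reproducible (%.1f%%), PCC %.4f\n",
              x$n_reproducible, x$n_detected,
              100 * x$fraction_reproducible, x$pcc))
  invisible(x)
}

#' Quantile-normalize an expression matrix
#'
#' After normalization every sample's sorted value vector equals the
#' across-sample mean of sorted vectors; within-sample ranks are preserved
#' and ties receive the average of the corresponding reference values. The
#' operation is idempotent.
#'
#' @param mat An [expression_matrix()] with >= 2 samples.
#' @return A quantile-normalized [expression_matrix()].
#' @export
quantile_normalize <- function(mat) {
  if (ncol(mat$values) < 2L) stop("need >= 2 samples")
  out <- limma::normalizeQuantiles(mat$values, ties = TRUE)
  dimnames(out) <- dimnames(mat$values)
  expression_matrix(out, unit = mat$unit, gene_meta = mat$gene_meta)
}

#' Detection-vs-depth downsampling curve
#'
#' Subsamples a read-count profile to each target depth (multinomial draws
#' with probabilities proportional to the observed counts; an exact
#' without-replacement mode draws a multivariate hypergeometric instead) and
#' reports, per depth, the number of detected genes and the log-scale Pearson
#' correlation with the full-depth profile. When `gene_lengths` is supplied,
#' FPKM is recomputed at each depth as
#' `count / (length_kb * depth_millions)` and detection uses `min_fpkm`;
#' otherwise detection is `count >= min_count`.
#'
#' @param counts Named nonnegative integer vector of per-gene read counts.
#' @param depths Target total read counts, each <= `sum(counts)`.
#' @param gene_lengths Optional transcript lengths (bp) aligned with `counts`.
#' @param min_fpkm Detection threshold when lengths are supplied (strict >).
#' @param min_count Detection threshold on raw counts otherwise (>=).
#' @param mode `"multinomial"` (with replacement, default) or `"exact"`
#'   (without replacement; reproduces `counts` exactly at full depth).
#' @param seed Integer seed.
#' @param pseudo_count Pseudo-count for the log-scale correlation.
#' @return data.frame with columns `depth`, `n_detected`, `pcc_vs_full`.
#' @export
downsample_detection <- function(counts, depths, gene_lengths = NULL,
                                 min_fpkm = 1, min_count = 1L,
                                 mode = c("multinomial", "exact"),
                                 seed = 1L, pseudo_count = 1) {
  mode <- match.arg(mode)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers")
  total <- sum(counts)
  if (any(depths > total))
    stop("depth exceeds total read count (no upsampling)")
  to_expr <- function(cnt, depth) {
    if (is.null(gene_lengths)) cnt
    else cnt / ((gene_lengths / 1000) * (depth / 1e6))
  }
  detect <- function(cnt, depth) {
    if (is.null(gene_lengths)) sum(cnt >= min_count)
    else sum(to_expr(cnt, depth) > min_fpkm)
  }
  full_expr <- to_expr(counts, total)
  res <- with_seed(derive_seed(seed, "downsample"), {
    lapply(depths, function(d) {
      cnt <- if (mode == "multinomial") {
        as.numeric(stats::rmultinom(1, d, counts / total))
      } else {
        draw_hypergeom(counts, d)
      }
      expr <- to_expr(cnt, d)
      pcc <- if (stats::sd(log10(expr + pseudo_count)) == 0 ||
                 stats::sd(log10(full_expr + pseudo_count)) == 0) NA_real_
             else stats::cor(log10(expr + pseudo_count),
                             log10(full_expr + pseudo_count))
      data.frame(depth = d, n_detected = detect(cnt, d), pcc_vs_full = pcc)
    })
  })
  do.call(rbind, res)
}

# sequential multivariate hypergeometric draw (without replacement)
draw_hypergeom <- function(counts, depth) {
  k <- length(counts)
  out <- numeric(k)
  remaining <- sum(counts)
  need <- depth
  for (g in seq_len(k)) {
    if (need == 0) break
    if (g == k) { out[g] <- need; break }
    x <- stats::rhyper(1, counts[g], remaining - counts[g], need)
    out[g] <- x
    need <- need - x
    remaining <- remaining - counts[g]
  }
  out
}
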