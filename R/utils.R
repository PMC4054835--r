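#' Area under the ROC curve by the rank statistic
#'
#' Probability that a randomly chosen positive scores above a randomly chosen
#' negative (ties count half), computed from the rank-sum identity.
#'
#' @param scores Numeric scores (higher = more positive-like); NAs dropped
#'   with their labels.
#' @param labels Logical vector of true positives.
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(scores, labels) {
  keep <- !is.na(scores)
  scores <- scores[keep]; labels <- labels[keep]
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) stop("need both positive and negative labels")
  r <- rank(scores)
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}
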