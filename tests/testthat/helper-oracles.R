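# Independent brute-force oracles and small fixture builders shared across
# the test files. Oracles deliberately re-derive quantities from first
# principles (explicit loops, closed forms, numeric integration) rather than
# calling the package code paths they check.

# James-Stein lambda* and shrunk frequencies, coded independently with loops
oracle_js <- function(counts) {
  n <- sum(counts)
  theta <- counts / n
  m <- length(counts)
  t_k <- 1 / m
  num <- 1 - sum(theta * theta)
  den <- 0
  for (i in seq_len(m)) den <- den + (t_k - theta[i])^2
  den <- (n - 1) * den
  lambda <- if (den == 0) 1 else num / den
  lambda <- min(1, max(0, lambda))
  list(lambda = lambda, p = lambda * t_k + (1 - lambda) * theta)
}

# plug-in entropy in bits via an explicit loop
oracle_entropy <- function(p) {
  h <- 0
  for (x in p) if (x > 0) h <- h - x * log2(x)
  h
}

# MI of a joint probability matrix as the Kullback-Leibler distance from the
# joint to the product of marginals
oracle_mi_kl <- function(joint) {
  px <- rowSums(joint)
  py <- colSums(joint)
  mi <- 0
  for (i in seq_len(nrow(joint))) for (j in seq_len(ncol(joint))) {
    p <- joint[i, j]
    if (p > 0) mi <- mi + p * log2(p / (px[i] * py[j]))
  }
  mi
}

# upper-tail F probability by numeric integration of the hand-written density
oracle_f_upper <- function(f, d1, d2) {
  dens <- function(x) {
    exp(lgamma((d1 + d2) / 2) - lgamma(d1 / 2) - lgamma(d2 / 2) +
          (d1 / 2) * log(d1 / d2) + (d1 / 2 - 1) * log(x) -
          ((d1 + d2) / 2) * log(1 + d1 * x / d2))
  }
  stats::integrate(dens, f, Inf, rel.tol = 1e-12, abs.tol = 1e-14)$value
}

# hypergeometric upper tail P(X >= k) by enumeration over all C(N, n) draws
oracle_hyper_upper <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  in_set <- seq_len(K)
  hits <- apply(draws, 2, function(d) sum(d %in% in_set))
  mean(hits >= k)
}

# contingency table wrapper used by the MI tests
ct <- function(counts) {
  list(counts = counts, n = sum(counts))
}

rand_matrix <- function(genes = 20, samples = 5, seed = 1) {
  set.seed(seed)
  v <- matrix(stats::rexp(genes * samples, rate = 0.1),
              nrow = genes,
              dimnames = list(sprintf("g%03d", seq_len(genes)),
                              sprintf("s%02d", seq_len(samples))))
  expression_matrix(v, unit = "FPKM")
}
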