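# Sample-structure analyses: PCA of cells on log-transformed expression,
# Ward hierarchical clustering (Newick export), and hypergeometric
# over-representation of gene sets.

transform_expression <- function(mat, pseudo_count = 1) {
  log10(mat$values + pseudo_count)
}

#' Principal components analysis of samples
#'
#' Samples are embedded on `log10(value + pseudo_count)`-transformed
#' expression with genes centered (not scaled). Components are orthonormal,
#' ordered by decreasing explained variance, and sign-fixed so the
#' largest-magnitude gene loading of each component is positive.
#'
#' @param mat An [expression_matrix()] with >= 2 samples.
#' @param n_components Number of components, `<= min(genes, samples - 1)`.
#' @param pseudo_count Pseudo-count for the log transform.
#' @return List with `scores` (samples x components), `loadings` (genes x
#'   components), `variance_explained` (fractions, sum <= 1), and
#'   `total_variance`.
#' @export
pca_embed <- function(mat, n_components = 3L, pseudo_count = 1) {
  if (ncol(mat$values) < 2L) stop("need >= 2 samples")
  x <- t(transform_expression(mat, pseudo_count))   # samples x genes
  if (all(apply(x, 2, stats::sd) == 0))
    stop("constant matrix: no variance to decompose")
  max_k <- min(nrow(x) - 1L, ncol(x))
  if (n_components > max_k)
    stop("n_components must be <= min(genes, samples - 1) = ", max_k)
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  k <- seq_len(n_components)
  load <- pc$rotation[, k, drop = FALSE]
  scores <- pc$x[, k, drop = FALSE]
  # fix signs: largest-|loading| gene positive per component
  for (j in k) {
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) {
      load[, j] <- -load[, j]
      scores[, j] <- -scores[, j]
    }
  }
  total <- sum(pc$sdev^2)
  list(scores = scores, loadings = load,
       variance_explained = pc$sdev[k]^2 / total,
       total_variance = total)
}

#' Ward hierarchical clustering of samples
#'
#' Agglomerative Ward linkage on Euclidean distances between
#' log-transformed sample profiles. Columns are ordered by sample id before
#' clustering so tie-breaking is deterministic and invariant to input column
#' order.
#'
#' @param mat An [expression_matrix()] with >= 2 samples and unique ids.
#' @param pseudo_count Pseudo-count for the log transform.
#' @return List with `hclust` (the tree), `newick` (serialized with branch
#'   lengths), and `cut2` (two-cluster membership named by sample).
#' @export
ward_cluster <- function(mat, pseudo_count = 1) {
  if (ncol(mat$values) < 2L) stop("need >= 2 samples")
  if (anyDuplicated(sample_ids(mat))) stop("duplicate sample ids")
  x <- transform_expression(mat, pseudo_count)
  x <- x[, order(colnames(x)), drop = FALSE]
  hc <- stats::hclust(stats::dist(t(x)), method = "ward.D2")
  newick <- ape::write.tree(ape::as.phylo(hc))
  cut2 <- if (ncol(x) >= 2L) stats::cutree(hc, k = 2L) else NULL
  list(hclust = hc, newick = newick, cut2 = cut2)
}

#' Hypergeometric over-representation analysis
#'
#' For each gene set, tests whether the selected genes overlap the set more
#' than expected by chance: `p = P(X >= k)` with X hypergeometric(N, K, n),
#' where N is the universe size, K the (universe-intersected) set size, n the
#' selection size and k the overlap. Benjamini-Hochberg q-values are computed
#' over the whole collection.
#'
#' @param selected Character vector of selected genes (subset of `universe`).
#' @param gene_sets Named list of character vectors ([read_gene_sets()]).
#' @param universe Character vector of all testable genes (non-empty).
#' @return data.frame, one row per set: `set_name`, `universe_size`,
#'   `set_size`, `selected_size`, `overlap`, `p_hyper`, `q_bh`.
#' @export
ora_hypergeom <- function(selected, gene_sets, universe) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  selected <- unique(selected)
  if (!all(selected %in% universe))
    stop("selected genes must be a subset of the universe")
  N <- length(universe)
  n <- length(selected)
  rows <- lapply(names(gene_sets), function(nm) {
    set <- intersect(unique(gene_sets[[nm]]), universe)
    K <- length(set)
    k <- length(intersect(selected, set))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set_name = nm, universe_size = N, set_size = K,
               selected_size = n, overlap = k, p_hyper = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_bh <- stats::p.adjust(out$p_hyper, method = "BH")
  out
}

#' Top genes by absolute loading on a principal component
#'
#' Selection rule feeding [ora_hypergeom()] per component.
#' @param pca Result of [pca_embed()].
#' @param component Component index.
#' @param m Number of genes (default 500).
#' @return Character vector of gene ids.
#' @export
top_loading_genes <- function(pca, component = 1L, m = 500L) {
  l <- pca$loadings[, component]
  names(sort(abs(l), decreasing = TRUE))[seq_len(min(m, length(l)))]
}
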