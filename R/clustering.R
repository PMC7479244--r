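#' Per-group completeness filter
#'
#' Keeps the sites covered (non-missing) in at least `min_per_group`
#' samples of *every* listed group — e.g. "each CpG10 covered in at least 4
#' bulls per group" before clustering or testing.
#'
#' @param x a [CountMatrix].
#' @param min_per_group minimum covered samples per group (inclusive).
#' @param groups group label per sample; defaults to
#'   `x$samples$group_label`.
#' @return a filtered [CountMatrix].
#' @export
completeness_filter <- function(x, min_per_group = 4L, groups = NULL) {
  stopifnot(inherits(x, "CountMatrix"))
  groups <- groups %||% x$samples$group_label
  if (length(groups) != nrow(x$samples))
    stop("group labels must cover all samples")
  sizes <- table(groups)
  if (min_per_group > min(sizes))
    stop(sprintf("min_per_group (%d) exceeds the size of group '%s' (%d)",
                 min_per_group, names(which.min(sizes)), min(sizes)))
  keep <- rep(TRUE, nrow(x$sites))
  for (g in unique(groups)) {
    cnt <- rowSums(!is.na(x$total[, groups == g, drop = FALSE]))
    keep <- keep & cnt >= min_per_group
  }
  subset_matrix(x, sites = keep)
}

#' Correlation distance between samples
#'
#' `d(i, j) = 1 - r(i, j)` with r the Pearson (or Spearman) correlation of
#' methylation percentages over the sites non-missing in both samples
#' (pairwise-complete).  Distances live in \[0, 2\]; perfectly correlated
#' samples are at 0, perfectly anti-correlated at 2.
#'
#' @param x a [CountMatrix] or a sites x samples percentage matrix.
#' @param method "pearson" or "spearman".
#' @param min_shared minimum number of shared sites per pair; a pair below
#'   it aborts with an error naming the pair.
#' @return symmetric distance matrix with zero diagonal.
#' @export
correlation_distance_matrix <- function(x, method = c("pearson", "spearman"),
                                        min_shared = 100L) {
  method <- match.arg(method)
  pct <- if (inherits(x, "CountMatrix")) percent_matrix(x) else as.matrix(x)
  if (ncol(pct) < 2) stop("need >= 2 samples")
  shared <- crossprod(!is.na(pct))
  off <- shared[upper.tri(shared)]
  if (any(off < max(2L, min_shared))) {
    idx <- which(shared == min(off) & upper.tri(shared), arr.ind = TRUE)[1, ]
    stop(sprintf("samples '%s' and '%s' share only %d sites (< %d)",
                 colnames(pct)[idx[1]], colnames(pct)[idx[2]],
                 min(off), max(2L, min_shared)))
  }
  r <- cor(pct, use = "pairwise.complete.obs", method = method)
  d <- 1 - r
  diag(d) <- 0
  d
}

#' Correlation-based hierarchical clustering of samples
#'
#' Agglomerative clustering of the correlation distance matrix (UPGMA /
#' average linkage by default).  Samples are ordered lexicographically by id
#' before clustering so that equal-distance merges are resolved
#' deterministically, independent of input order.
#'
#' @param distances symmetric distance matrix (e.g. from
#'   [correlation_distance_matrix()]).
#' @param linkage an `hclust` agglomeration method; default "average".
#' @return list of class `sample_dendrogram`: `hclust`, `phylo` (an
#'   [ape::phylo] tree with branch lengths in correlation-distance units)
#'   and `linkage`.
#' @export
hierarchical_cluster <- function(distances, linkage = "average") {
  distances <- as.matrix(distances)
  if (!isSymmetric(unname(distances), tol = 1e-8))
    stop("distance matrix must be symmetric")
  ord <- order(colnames(distances))
  distances <- distances[ord, ord]
  hc <- hclust(as.dist(distances), method = linkage)
  out <- list(hclust = hc, phylo = ape::as.phylo(hc), linkage = linkage)
  class(out) <- "sample_dendrogram"
  out
}

#' @export
print.sample_dendrogram <- function(x, ...) {
  cat(sprintf("sample dendrogram: %d leaves, %s linkage\n",
              length(x$hclust$labels), x$linkage))
  invisible(x)
}

#' Cluster a CountMatrix end to end
#'
#' Convenience wrapper: completeness filter, correlation distance,
#' hierarchical clustering, and a flat cut.
#'
#' @param x a [CountMatrix].
#' @param min_per_group completeness threshold (see
#'   [completeness_filter()]).
#' @param k number of flat clusters to report.
#' @param method,linkage,min_shared passed through.
#' @return list with `matrix` (filtered), `distances`, `tree`
#'   (`sample_dendrogram`) and `clusters` (named integer vector).
#' @export
cluster_samples <- function(x, min_per_group = 4L, k = 2L,
                            method = "pearson", linkage = "average",
                            min_shared = 100L) {
  xf <- completeness_filter(x, min_per_group)
  d <- correlation_distance_matrix(xf, method = method,
                                   min_shared = min_shared)
  tree <- hierarchical_cluster(d, linkage = linkage)
  list(matrix = xf, distances = d, tree = tree,
       clusters = cutree(tree$hclust, k = k))
}

#' Write a dendrogram as Newick
#'
#' @param tree a `sample_dendrogram`.
#' @param path output file.
#' @return invisibly, the path.
#' @export
export_newick <- function(tree, path) {
  stopifnot(inherits(tree, "sample_dendrogram"))
  ape::write.tree(tree$phylo, file = path)
  invisible(path)
}
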