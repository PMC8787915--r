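#' Hierarchical agglomerative clustering with Ward and UPGMA linkages
#'
#' Agglomerates a precomputed dissimilarity matrix with Lance--Williams
#' updates and cuts the tree at `k` clusters. Three linkages are supported:
#' \describe{
#'   \item{`ward2`}{Ward's criterion applied to squared dissimilarities,
#'     merge heights reported on the original scale (square root); the
#'     package default.}
#'   \item{`ward1`}{Ward's recursion applied to the dissimilarities as
#'     given.}
#'   \item{`upgma`}{unweighted pair-group average linkage.}
#' }
#' Ties in the minimum inter-cluster distance are broken deterministically:
#' the pair with the lexicographically smallest cluster indices (leaves
#' first, then merge order) is merged first, so results are identical across
#' platforms.
#'
#' @param D symmetric non-negative dissimilarity matrix with zero diagonal
#'   (e.g. from [pairwise_dtw()]).
#' @param linkage one of `"ward2"`, `"ward1"`, `"upgma"`.
#' @param k number of clusters, `2 <= k <= n - 1`.
#' @return object of class `atn_clustering`: `labels` (1..k, numbered by
#'   first subject appearance), `k`, `linkage`, `merge` (hclust-style),
#'   `height` (non-decreasing), `n`, and `subject_ids`.
#' @export
#' @examples
#' x <- c(rnorm(10), rnorm(10, 50))
#' D <- abs(outer(x, x, "-"))
#' table(hierarchical_cluster(D, "ward2", k = 2)$labels)
hierarchical_cluster <- function(D, linkage = c("ward2", "ward1", "upgma"),
                                 k = 2L) {
  linkage <- match.arg(linkage)
  D <- as.matrix(D)
  n <- nrow(D)
  if (!isTRUE(all.equal(D, t(D), tolerance = 1e-10)))
    abort("dissimilarity matrix must be symmetric", "atnprog_matrix_error")
  if (any(!is.finite(D)) || any(D < 0) || any(abs(diag(D)) > 1e-12))
    abort("dissimilarity matrix must be finite, non-negative, zero-diagonal",
          "atnprog_matrix_error")
  if (k < 2L || k > n - 1L)
    abort("k must satisfy 2 <= k <= n - 1", "atnprog_config_error")

  tree <- lw_agglomerate(D, linkage)
  labels <- cut_merge_tree(tree$merge, n, k)
  structure(list(labels = labels, k = as.integer(k), linkage = linkage,
                 merge = tree$merge, height = tree$height, n = n,
                 subject_ids = rownames(D)),
            class = "atn_clustering")
}

# Lance-Williams agglomeration over a (2n-1)-slot distance matrix.
# Cluster ids: leaves 1..n, merges n+1..2n-1 in creation order.
lw_agglomerate <- function(D, linkage) {
  n <- nrow(D)
  W <- if (linkage == "ward2") D^2 else D
  total <- 2L * n - 1L
  M <- matrix(Inf, total, total)
  M[1:n, 1:n] <- W
  diag(M) <- Inf
  size <- c(rep(1, n), rep(0, n - 1L))
  alive <- c(rep(TRUE, n), rep(FALSE, n - 1L))
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)

  for (s in seq_len(n - 1L)) {
    act <- which(alive)
    A <- M[act, act, drop = FALSE]
    mv <- min(A)
    hit <- which(A == mv, arr.ind = TRUE)
    # map to cluster ids, keep i < j, lexicographic smallest pair
    pi <- act[hit[, 1L]]; pj <- act[hit[, 2L]]
    lo <- pmin(pi, pj); hi <- pmax(pi, pj)
    ord <- order(lo, hi)
    i <- lo[ord[1L]]; j <- hi[ord[1L]]
    new <- n + s
    height[s] <- mv
    merge[s, ] <- c(if (i <= n) -i else i - n, if (j <= n) -j else j - n)

    others <- act[act != i & act != j]
    if (length(others)) {
      di <- M[i, others]; dj <- M[j, others]; dij <- mv
      ni <- size[i]; nj <- size[j]; nk <- size[others]
      upd <- switch(linkage,
        upgma = (ni * di + nj * dj) / (ni + nj),
        ward1 = ,
        ward2 = ((nk + ni) * di + (nk + nj) * dj - nk * dij) /
          (nk + ni + nj))
      M[new, others] <- upd
      M[others, new] <- upd
    }
    alive[c(i, j)] <- FALSE
    alive[new] <- TRUE
    size[new] <- size[i] + size[j]
  }
  if (linkage == "ward2") height <- sqrt(height)
  list(merge = merge, height = height)
}

# Assign leaves to k clusters by applying the first n-k merges (union-find),
# numbering clusters 1..k in order of first leaf appearance.
cut_merge_tree <- function(merge, n, k) {
  parent <- seq_len(n)
  cluster_of_merge <- integer(nrow(merge))
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (s in seq_len(n - k)) {
    a <- merge[s, 1L]; b <- merge[s, 2L]
    ra <- if (a < 0) find(-a) else find(cluster_of_merge[a])
    rb <- if (b < 0) find(-b) else find(cluster_of_merge[b])
    parent[rb] <- ra
    cluster_of_merge[s] <- ra
  }
  if (n - k < nrow(merge))
    for (s in seq.int(n - k + 1L, nrow(merge)))
      cluster_of_merge[s] <- NA_integer_
  roots <- vapply(seq_len(n), find, integer(1))
  labels <- match(roots, unique(roots))
  labels
}

#' @export
print.atn_clustering <- function(x, ...) {
  cat(sprintf("Hierarchical clustering (%s linkage), k = %d, n = %d\n",
              x$linkage, x$k, x$n))
  print(table(cluster = x$labels))
  if (!is.null(x$phenotype))
    print(table(phenotype = x$phenotype))
  invisible(x)
}

#' Convert a clustering tree to an `hclust` object
#'
#' Enables standard dendrogram plotting and Newick export via
#' `ape::as.phylo`.
#'
#' @param x an `atn_clustering`.
#' @param ... unused.
#' @return an object of class `hclust`.
#' @exportS3Method stats::as.hclust
as.hclust.atn_clustering <- function(x, ...) {
  ord <- integer(0)
  expand <- function(id) {
    if (id < 0) return(-id)
    c(expand(x$merge[id, 1L]), expand(x$merge[id, 2L]))
  }
  ord <- expand(nrow(x$merge))
  structure(list(merge = x$merge, height = x$height, order = ord,
                 labels = x$subject_ids %||% as.character(seq_len(x$n)),
                 method = x$linkage, call = match.call(),
                 dist.method = "dtw"),
            class = "hclust")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-sample silhouette widths from a dissimilarity matrix
#'
#' \eqn{s(i) = (b(i) - a(i)) / max(a(i), b(i))} where \eqn{a(i)} is the mean
#' dissimilarity to the subject's own cluster (excluding itself) and
#' \eqn{b(i)} the smallest mean dissimilarity to any other cluster.
#' Singleton clusters receive \eqn{s(i) = 0}.
#'
#' @param D dissimilarity matrix.
#' @param labels integer cluster labels.
#' @return numeric vector of widths in \[-1, 1\].
#' @export
silhouette_widths <- function(D, labels) {
  D <- as.matrix(D)
  n <- nrow(D)
  labels <- as.integer(factor(labels))
  ks <- sort(unique(labels))
  sums <- t(rowsum(D, labels))            # n x k: sum of dists to each cluster
  sizes <- tabulate(labels, max(ks))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels[i]
    if (sizes[own] == 1L) { s[i] <- 0; next }
    a <- sums[i, own] / (sizes[own] - 1L)
    b <- min(sums[i, ks[ks != own]] / sizes[ks[ks != own]])
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  s
}

#' Select the number of clusters by average silhouette width
#'
#' Clusters the dissimilarity matrix with [hierarchical_cluster()] for each
#' candidate `k` and returns the `k` maximising the average silhouette width
#' (smallest `k` on ties).
#'
#' @param D dissimilarity matrix.
#' @param k_range candidate cluster counts (default 2:4).
#' @param linkage linkage passed to [hierarchical_cluster()].
#' @return list with `k` (selected), `avg_width` (named vector) and
#'   `widths` (per-sample widths for the selected k).
#' @export
silhouette_select_k <- function(D, k_range = 2:4, linkage = "ward2") {
  D <- as.matrix(D)
  n <- nrow(D)
  if (all(D == 0))
    abort("silhouette undefined: all dissimilarities are zero",
          "atnprog_degenerate_error")
  if (any(k_range < 2L) || any(k_range > n - 1L))
    abort("k_range must lie within [2, n - 1]", "atnprog_config_error")
  widths <- lapply(k_range, function(k)
    silhouette_widths(D, hierarchical_cluster(D, linkage, k)$labels))
  avg <- vapply(widths, mean, numeric(1))
  names(avg) <- paste0("k", k_range)
  best <- which.max(avg)  # first max = smallest k on ties
  list(k = k_range[best], avg_width = avg, widths = widths[[best]])
}
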