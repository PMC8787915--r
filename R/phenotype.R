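#' Name the two clusters as moderate/fast decliner phenotypes
#'
#' For a 2-cluster solution, fits a least-squares slope per subject
#' (score against years since baseline), averages slopes per cluster and
#' names the cluster with the more negative mean slope the fast decliners
#' (FD); the other becomes the moderate decliners (MD). Exact slope ties are
#' broken toward the larger baseline mean being MD.
#'
#' @param assignment an `atn_clustering` with `k = 2`.
#' @param trajectories subjects-by-visits score matrix (or cohort
#'   `trajectories` list) in the same subject order as the clustering.
#' @return the assignment augmented with `phenotype` (factor MD/FD per
#'   subject) and `phenotype_map` (cluster index to phenotype).
#' @export
name_phenotypes <- function(assignment, trajectories) {
  if (!inherits(assignment, "atn_clustering") || assignment$k != 2L)
    abort("phenotype naming requires a 2-cluster assignment",
          "atnprog_naming_error")
  x <- if (is.list(trajectories) && !is.data.frame(trajectories))
    trajectories else list(scores = as.matrix(trajectories),
                           visit_months = NULL)
  scores <- as.matrix(x$scores)
  months <- x$visit_months %||% (seq_len(ncol(scores)) - 1) * 12
  if (nrow(scores) != length(assignment$labels))
    abort("trajectories and assignment cover different subjects",
          "atnprog_naming_error")
  ty <- months / 12
  txc <- ty - mean(ty)
  slopes <- as.numeric(scores %*% txc) / sum(txc^2)
  m1 <- mean(slopes[assignment$labels == 1L])
  m2 <- mean(slopes[assignment$labels == 2L])
  if (m1 == m2) {
    b1 <- mean(scores[assignment$labels == 1L, 1L])
    b2 <- mean(scores[assignment$labels == 2L, 1L])
    fd <- if (b1 >= b2) 2L else 1L  # larger baseline mean stays MD
  } else {
    fd <- if (m1 < m2) 1L else 2L
  }
  map <- c("MD", "MD")
  map[fd] <- "FD"
  assignment$phenotype_map <- setNames(map, c("1", "2"))
  assignment$phenotype <- factor(map[assignment$labels],
                                 levels = c("MD", "FD"))
  assignment$cluster_mean_slope <- setNames(c(m1, m2), c("1", "2"))
  assignment
}

#' Cluster cognitive trajectories into progression phenotypes
#'
#' Convenience wrapper over the full trajectory-clustering chain: pairwise
#' DTW distances, hierarchical clustering, optional silhouette-based
#' selection of the number of clusters, and (when the solution has two
#' clusters) phenotype naming.
#'
#' @param trajectories subjects-by-visits score matrix or cohort
#'   `trajectories` list.
#' @param linkage linkage for [hierarchical_cluster()].
#' @param k integer number of clusters, or `"auto"` for silhouette selection
#'   over `k_range`.
#' @param k_range candidate `k` values when `k = "auto"`.
#' @return an `atn_clustering`, with `phenotype` when `k = 2`, plus a
#'   `silhouette` element when selection ran.
#' @export
cluster_phenotypes <- function(trajectories, linkage = "ward2", k = "auto",
                               k_range = 2:4) {
  D <- pairwise_dtw(trajectories)
  sil <- NULL
  if (identical(k, "auto")) {
    sil <- silhouette_select_k(D, k_range, linkage)
    k <- sil$k
  }
  cl <- hierarchical_cluster(D, linkage, k)
  if (k == 2L) cl <- name_phenotypes(cl, trajectories)
  cl$silhouette <- sil
  cl$distance <- D
  cl
}
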