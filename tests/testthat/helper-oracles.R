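# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# All monotone warping paths from (1,1) to (n,m) with steps
# {(1,0),(0,1),(1,1)}; exhaustive enumeration is feasible for lengths <= 6.
enumerate_warping_paths <- function(n, m) {
  if (n == 1L && m == 1L) return(list(matrix(c(1L, 1L), 1L)))
  out <- list()
  add <- function(paths) for (p in paths)
    out[[length(out) + 1L]] <<- rbind(p, c(n, m))
  if (n > 1L) add(enumerate_warping_paths(n - 1L, m))
  if (m > 1L) add(enumerate_warping_paths(n, m - 1L))
  if (n > 1L && m > 1L) add(enumerate_warping_paths(n - 1L, m - 1L))
  out
}

dtw_bruteforce <- function(a, b) {
  paths <- enumerate_warping_paths(length(a), length(b))
  min(vapply(paths, function(p) sum(abs(a[p[, 1]] - b[p[, 2]])),
             numeric(1)))
}

# Naive O(n^3) agglomerator: scalar loops, full rescan of the current
# cluster-distance matrix at every step, UPGMA distances recomputed from the
# ORIGINAL matrix (not the recursion). Tie-break: lowest creation-id pair.
naive_agglomerate <- function(D, linkage) {
  n <- nrow(D)
  W <- if (linkage == "ward2") D^2 else D
  members <- as.list(seq_len(n))
  ids <- seq_len(n)
  cd <- W
  sizes <- rep(1, n)
  heights <- numeric(n - 1L)
  partitions <- list()
  for (s in seq_len(n - 1L)) {
    k <- length(members)
    best <- Inf; bi <- 0L; bj <- 0L
    for (i in seq_len(k - 1L)) for (j in seq.int(i + 1L, k)) {
      v <- cd[i, j]
      pair <- sort(c(ids[i], ids[j]))
      if (v < best ||
          (v == best && (pair[1] < sort(c(ids[bi], ids[bj]))[1] ||
                         (pair[1] == sort(c(ids[bi], ids[bj]))[1] &&
                          pair[2] < sort(c(ids[bi], ids[bj]))[2])))) {
        best <- v; bi <- i; bj <- j
      }
    }
    heights[s] <- best
    new_members <- c(members[[bi]], members[[bj]])
    new_size <- sizes[bi] + sizes[bj]
    keep <- setdiff(seq_len(k), c(bi, bj))
    new_cd <- matrix(0, k - 1L, k - 1L)
    if (length(keep)) {
      new_cd[seq_along(keep), seq_along(keep)] <- cd[keep, keep]
      for (t in seq_along(keep)) {
        kk <- keep[t]
        v <- if (linkage == "upgma") {
          mean(D[new_members, members[[kk]]])
        } else {
          ((sizes[kk] + sizes[bi]) * cd[kk, bi] +
             (sizes[kk] + sizes[bj]) * cd[kk, bj] -
             sizes[kk] * cd[bi, bj]) / (sizes[kk] + new_size)
        }
        new_cd[t, k - 1L] <- v
        new_cd[k - 1L, t] <- v
      }
    }
    members <- c(members[keep], list(new_members))
    ids <- c(ids[keep], n + s)
    sizes <- c(sizes[keep], new_size)
    cd <- new_cd
    partitions[[s]] <- members
  }
  if (linkage == "ward2") heights <- sqrt(heights)
  list(heights = heights, partitions = partitions)
}

# Partition (list of member index sets) -> label vector for n leaves.
partition_labels <- function(members, n) {
  lab <- integer(n)
  for (i in seq_along(members)) lab[members[[i]]] <- i
  lab
}

# Random symmetric dissimilarity matrix with zero diagonal.
random_dissimilarity <- function(n) {
  x <- matrix(rnorm(n * 3), n)
  as.matrix(dist(x))
}

# Chance-corrected partition agreement, via mclust (independent of the
# package's clustering code).
ari_oracle <- function(a, b) mclust::adjustedRandIndex(a, b)
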