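test_that("dtw_distance matches hand-computed and brute-force values", {
  expect_identical(dtw_distance(c(3, 1, 4), c(3, 1, 4)), 0)
  expect_identical(dtw_distance(c(0, 0), c(1, 1)), 2)
  set.seed(42)
  for (i in 1:40) {
    a <- rnorm(sample(2:6, 1)) * 5
    b <- rnorm(sample(2:6, 1)) * 5
    d <- dtw_distance(a, b)
    expect_identical(d, dtw_distance(b, a))
    expect_equal(d, dtw_bruteforce(a, b), tolerance = 1e-12)
  }
})

test_that("dtw rejects empty and missing inputs without imputation", {
  expect_error(dtw_distance(numeric(0), 1), class = "atnprog_length_error")
  expect_error(dtw_distance(c(1, NA), c(1, 2)),
               class = "atnprog_missing_data_error")
})

test_that("pairwise_dtw fills the matrix symmetrically and drops missing rows", {
  x <- rbind(c(0, 0), c(1, 1), c(2, 2))
  D <- pairwise_dtw(x)
  expect_equal(D[upper.tri(D)], c(2, 4, 2))
  expect_identical(D, t(D))
  x2 <- rbind(c(1, 2), c(1, 2))
  expect_true(all(pairwise_dtw(x2) == 0))
  x3 <- rbind(x, c(NA, NA))
  expect_warning(D3 <- pairwise_dtw(x3), "missing")
  expect_equal(dim(D3), c(3L, 3L))
})

test_that("permuting subject order permutes the distance matrix identically", {
  set.seed(9)
  x <- matrix(rnorm(8 * 4), 8)
  D <- pairwise_dtw(x)
  p <- sample(8)
  expect_equal(pairwise_dtw(x[p, ]), D[p, p], ignore_attr = TRUE)
})

test_that("UPGMA merge heights equal hand-computed average-linkage values", {
  D <- matrix(0, 4, 4)
  D[1, 2] <- 1; D[3, 4] <- 2; D[1, 3] <- 5; D[1, 4] <- 6
  D[2, 3] <- 7; D[2, 4] <- 8
  D <- D + t(D)
  cl <- hierarchical_cluster(D, "upgma", k = 2)
  # {1,2} at 1, {3,4} at 2, then mean(5,6,7,8) = 6.5
  expect_equal(cl$height, c(1, 2, 6.5))
  expect_equal(cl$labels, c(1, 1, 2, 2))
})

test_that("well-separated point clouds are recovered exactly at k = 2", {
  set.seed(4)
  x <- c(rnorm(12, 0, 1), rnorm(10, 300, 1))
  D <- abs(outer(x, x, "-"))
  for (lk in c("ward2", "ward1", "upgma")) {
    cl <- hierarchical_cluster(D, lk, 2)
    expect_equal(ari_oracle(cl$labels, rep(1:2, c(12, 10))), 1)
  }
})

test_that("all linkages match the naive rescanning agglomerator", {
  set.seed(14)
  for (i in 1:8) {
    D <- random_dissimilarity(sample(10:15, 1))
    for (lk in c("ward2", "ward1", "upgma")) {
      mine <- hierarchical_cluster(D, lk, k = 3)
      oracle <- naive_agglomerate(D, lk)
      expect_equal(mine$height, oracle$heights, tolerance = 1e-9)
      olab <- partition_labels(oracle$partitions[[nrow(D) - 3L]], nrow(D))
      expect_equal(ari_oracle(mine$labels, olab), 1)
    }
  }
})

test_that("linkages agree with stats::hclust on tie-free matrices", {
  set.seed(15)
  map <- c(ward2 = "ward.D2", ward1 = "ward.D", upgma = "average")
  for (i in 1:5) {
    D <- random_dissimilarity(12)
    for (lk in names(map)) {
      mine <- hierarchical_cluster(D, lk, k = 4)
      hc <- hclust(as.dist(D), method = map[[lk]])
      expect_equal(sort(mine$height), sort(hc$height), tolerance = 1e-9)
      expect_equal(ari_oracle(mine$labels, cutree(hc, 4)), 1)
    }
  }
})

test_that("clustering is deterministic under exact ties (lowest pair first)", {
  D <- matrix(1, 5, 5); diag(D) <- 0
  cl1 <- hierarchical_cluster(D, "upgma", 2)
  cl2 <- hierarchical_cluster(D, "upgma", 2)
  expect_identical(cl1$merge, cl2$merge)
  expect_equal(cl1$merge[1, ], c(-1, -2))  # leaves 1,2 merge first
})

test_that("clustering rejects invalid matrices and k", {
  D <- random_dissimilarity(6)
  Dn <- D; Dn[1, 2] <- Dn[1, 2] + 1  # asymmetric
  expect_error(hierarchical_cluster(Dn, "ward2", 2),
               class = "atnprog_matrix_error")
  expect_error(hierarchical_cluster(D, "ward2", 1),
               class = "atnprog_config_error")
  expect_error(hierarchical_cluster(D, "ward2", 6),
               class = "atnprog_config_error")
})

test_that("silhouette widths are bounded and ideal clusters score 1", {
  set.seed(20)
  D <- random_dissimilarity(20)
  lab <- hierarchical_cluster(D, "ward2", 3)$labels
  s <- silhouette_widths(D, lab)
  expect_true(all(s >= -1 & s <= 1))
  # two ideal clusters: zero within, unit between
  Dp <- matrix(1, 6, 6)
  Dp[1:3, 1:3] <- 0; Dp[4:6, 4:6] <- 0
  expect_equal(mean(silhouette_widths(Dp, rep(1:2, each = 3))), 1)
  sel <- silhouette_select_k(Dp, 2:4)
  expect_equal(sel$k, 2)
  expect_equal(unname(sel$avg_width["k2"]), 1)
  expect_error(silhouette_select_k(matrix(0, 5, 5)),
               class = "atnprog_degenerate_error")
})

test_that("silhouette agrees with cluster::silhouette when available", {
  skip_if_not_installed("cluster")
  set.seed(21)
  D <- random_dissimilarity(25)
  lab <- hierarchical_cluster(D, "upgma", 3)$labels
  ref <- cluster::silhouette(lab, dmatrix = D)
  expect_equal(silhouette_widths(D, lab), unname(ref[, "sil_width"]),
               tolerance = 1e-12)
})

test_that("phenotype naming follows mean slope with baseline tie-break", {
  # slopes -1 vs -4 per year over months 0..24
  months <- c(0, 6, 12, 24)
  mk <- function(b, slope, n) t(replicate(n, b + slope * months / 12))
  sc <- rbind(mk(28, -1, 5), mk(28, -4, 5))
  D <- pairwise_dtw(sc)
  cl <- hierarchical_cluster(D, "ward2", 2)
  named <- name_phenotypes(cl, list(scores = sc, visit_months = months))
  expect_equal(as.character(named$phenotype),
               rep(c("MD", "FD"), each = 5))
  # equal slopes, baselines 28 vs 22: larger baseline is MD
  sc2 <- rbind(mk(28, -2, 5), mk(22, -2, 5))
  cl2 <- hierarchical_cluster(pairwise_dtw(sc2), "ward2", 2)
  named2 <- name_phenotypes(cl2, list(scores = sc2, visit_months = months))
  expect_equal(as.character(named2$phenotype),
               rep(c("MD", "FD"), each = 5))
  expect_error(name_phenotypes(hierarchical_cluster(pairwise_dtw(sc), "ward2", 3),
                               sc), class = "atnprog_naming_error")
})

test_that("noise-free cohort phenotypes match generator classes exactly", {
  coh <- generate_cohort(noisefree_config(n = 24))
  cl <- cluster_phenotypes(coh$trajectories, k = 2)
  expect_equal(as.character(cl$phenotype), as.character(coh$true_class))
})

test_that("clustering is invariant to subject ordering", {
  coh <- generate_cohort(cohort_config(n_subjects = 40, seed = 31,
                                       generate_volumes = FALSE))
  sc <- coh$trajectories$scores
  cl <- cluster_phenotypes(list(scores = sc, visit_months = c(0, 6, 12, 24)),
                           k = 2)
  set.seed(1)
  p <- sample(nrow(sc))
  clp <- cluster_phenotypes(list(scores = sc[p, ],
                                 visit_months = c(0, 6, 12, 24)), k = 2)
  expect_equal(as.character(clp$phenotype),
               as.character(cl$phenotype)[p])
})

test_that("ward variants and UPGMA give similar partitions on default cohorts", {
  # linkage agreement is realization-dependent (a linkage can cut off a
  # small outlier cluster at k = 2), so the similarity claim is asserted
  # in aggregate over fixed seeds
  min_ari <- vapply(1:6, function(s) {
    coh <- generate_cohort(cohort_config(n_subjects = 120, seed = s,
                                         generate_volumes = FALSE))
    D <- pairwise_dtw(coh$trajectories$scores)
    labs <- lapply(c("ward2", "ward1", "upgma"),
                   function(lk) hierarchical_cluster(D, lk, 2)$labels)
    min(ari_oracle(labs[[1]], labs[[2]]), ari_oracle(labs[[1]], labs[[3]]),
        ari_oracle(labs[[2]], labs[[3]]))
  }, numeric(1))
  expect_gte(mean(min_ari), 0.8)
  expect_gte(sum(min_ari >= 0.9), 4)
})
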