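test_that("permutation test saturates on noise-free separated classes", {
  coh <- generate_cohort(noisefree_config(n = 24))
  cl <- cluster_phenotypes(coh$trajectories, k = 2)
  pt <- permutation_cluster_test(coh$trajectories, cl$phenotype,
                                 n_perm = 199, seed = 5)
  expect_equal(pt$p_value, 1 / 200)
  pt2 <- permutation_cluster_test(coh$trajectories, cl$phenotype,
                                  n_perm = 199, seed = 5)
  expect_identical(pt$p_value, pt2$p_value)  # deterministic given seed
})

test_that("permutation test rejects degenerate inputs", {
  coh <- generate_cohort(noisefree_config(n = 12))
  labs <- factor(c("A", rep("B", 11)))
  expect_error(permutation_cluster_test(coh$trajectories, labs, 100, 1),
               class = "atnprog_degenerate_cluster_error")
  expect_error(permutation_cluster_test(coh$trajectories, coh$true_class,
                                        n_perm = 50, seed = 1),
               class = "atnprog_config_error")
})

test_that("rm_anova matches a from-scratch sums-of-squares oracle", {
  # balanced 4 subjects (2 per group) x 3 times, hand-checkable numbers
  scores <- rbind(c(10, 9, 7), c(11, 9, 8), c(10, 8, 4), c(12, 9, 5))
  group <- factor(c("MD", "MD", "FD", "FD"), levels = c("MD", "FD"))
  res <- rm_anova(scores, group)

  # oracle: textbook mixed-design decomposition, written independently
  n <- 4; t <- 3; g <- 2
  grand <- mean(scores)
  time_means <- colMeans(scores)
  cell_means <- rbind(colMeans(scores[1:2, ]), colMeans(scores[3:4, ]))
  subj_means <- rowMeans(scores)
  ss_time <- n * sum((time_means - grand)^2)
  ss_cells <- 2 * sum((cell_means - grand)^2)
  grp_means <- rowMeans(cell_means)
  ss_group <- (n / g) * t * sum((grp_means - grand)^2)
  ss_int <- ss_cells - ss_time - ss_group
  ss_total <- sum((scores - grand)^2)
  ss_subj <- t * sum((subj_means - grand)^2)
  ss_err_within <- ss_total - ss_subj - ss_time - ss_int
  df_err <- (n - g) * (t - 1)
  expect_equal(res$F_time, (ss_time / (t - 1)) / (ss_err_within / df_err),
               tolerance = 1e-10)
  expect_equal(res$F_interaction,
               (ss_int / (t - 1)) / (ss_err_within / df_err),
               tolerance = 1e-10)
  expect_equal(res$df_time, c(t - 1, df_err))
  expect_equal(res$df_interaction, c(t - 1, df_err))
})

test_that("rm_anova handles constant scores and enforces balance", {
  scores <- matrix(5, 6, 4)
  res <- rm_anova(scores, rep(c("a", "b"), each = 3))
  expect_equal(res$F_time, 0)
  expect_equal(res$F_interaction, 0)
  expect_equal(res$p_time, 1)
  sc2 <- matrix(rnorm(24), 6); sc2[2, 3] <- NA
  expect_error(rm_anova(sc2, rep(c("a", "b"), each = 3)),
               class = "atnprog_balance_error")
})

test_that("rm_anova F statistics are shift- and relabel-invariant", {
  set.seed(8)
  scores <- matrix(rnorm(40), 10) + outer(rep(0, 10), c(0, 1, 2, 3))
  grp <- rep(c("MD", "FD"), each = 5)
  a <- rm_anova(scores, grp)
  b <- rm_anova(scores + 100, grp)
  cc <- rm_anova(scores, rev(grp))
  expect_equal(a$F_time, b$F_time, tolerance = 1e-10)
  expect_equal(a$F_interaction, b$F_interaction, tolerance = 1e-10)
  expect_equal(a$F_time, cc$F_time, tolerance = 1e-10)
})

test_that("interaction test holds its level under a pure time effect", {
  set.seed(99)
  rej <- mean(replicate(300, {
    sc <- matrix(rnorm(48), 12) + outer(rep(0, 12), c(0, 1, 2, 3))
    rm_anova(sc, rep(c("MD", "FD"), each = 6))$p_interaction < 0.05
  }))
  ci <- qbinom(c(0.025, 0.975), 300, 0.05) / 300
  expect_gte(rej, ci[1])
  expect_lte(rej, ci[2])
})

test_that("group_difference matches the Welch formula and flags degeneracy", {
  x <- c(5, 7, 9, 6, 8, 10); y <- c(1, 2, 3, 2, 1, 3)
  gd <- group_difference(c(x, y), rep(c("a", "b"), each = 6), "t")
  tstat <- (mean(x) - mean(y)) /
    sqrt(var(x) / length(x) + var(y) / length(y))
  expect_equal(gd$statistic, tstat, tolerance = 1e-12)
  # identical groups: rank-sum p-value is 1
  gr <- group_difference(rep(c(1, 2, 3), 2), rep(c("a", "b"), each = 3),
                         "ranksum")
  expect_equal(gr$p_value, 1)
  # power sanity
  set.seed(2)
  gp <- group_difference(c(rnorm(50), rnorm(50, 3)),
                         rep(c("a", "b"), each = 50), "t")
  expect_lt(gp$p_value, 1e-6)
  expect_error(group_difference(rep(1, 10), rep(c("a", "b"), each = 5), "t"),
               class = "atnprog_degenerate_group_error")
})

test_that("tau positivity is a strict elementwise threshold", {
  expect_identical(tau_positive(c(10, 22, 21.8, 30)),
                   c(FALSE, TRUE, FALSE, TRUE))
  expect_true(tau_positive(25))
  expect_false(tau_positive(21.8))
  expect_warning(res <- tau_positive(c(10, NA)), "missing")
  expect_identical(res, c(FALSE, NA))
})

test_that("chi_square matches hand computations and the 2x2 closed form", {
  r0 <- chi_square(matrix(c(10, 10, 10, 10), 2))
  expect_equal(r0$chi2, 0)
  expect_equal(r0$p, 1)

  # subtype-by-phenotype counts as printed: hand Pearson gives ~2.616
  tab <- rbind(c(19, 7), c(26, 21), c(13, 11))
  res <- chi_square(tab)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  hand <- sum((tab - expected)^2 / expected)
  expect_equal(res$chi2, hand, tolerance = 1e-12)
  expect_equal(res$chi2, 2.6158, tolerance = 1e-4)
  expect_equal(res$df, 2)

  set.seed(3)
  for (i in 1:20) {
    m <- matrix(sample(1:50, 4, replace = TRUE), 2)
    a <- m[1, 1]; b <- m[1, 2]; cc <- m[2, 1]; d <- m[2, 2]
    closed <- sum(m) * (a * d - b * cc)^2 /
      ((a + b) * (cc + d) * (a + cc) * (b + d))
    expect_equal(chi_square(m)$chi2, closed, tolerance = 1e-12)
  }
})

test_that("chi_square is permutation-invariant and rejects bad margins", {
  set.seed(4)
  m <- matrix(sample(5:30, 6), 3)
  base <- chi_square(m)$chi2
  expect_equal(chi_square(m[c(2, 3, 1), ])$chi2, base, tolerance = 1e-12)
  expect_equal(chi_square(m[, c(2, 1)])$chi2, base, tolerance = 1e-12)
  expect_error(chi_square(rbind(c(0, 0), c(3, 4))),
               class = "atnprog_margin_error")
  expect_error(chi_square(matrix(c(1.5, 2, 3, 4), 2)),
               class = "atnprog_config_error")
})
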