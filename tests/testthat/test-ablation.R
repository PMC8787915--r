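test_that("auc matches pair counting, limits and tie convention", {
  expect_equal(auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_equal(auc(c(1, 2, 3, 10, 11), c(0, 0, 0, 1, 1)), 1)
  expect_equal(auc(rep(0.3, 6), c(0, 1, 0, 1, 0, 1)), 0.5)
  expect_error(auc(1:4, rep(1, 4)), class = "atnprog_undefined_auc_error")
})

test_that("ROC trapezoid equals the Mann-Whitney AUC with ties", {
  trapezoid <- function(roc) {
    sum(diff(roc$fpr) * (head(roc$tpr, -1) + tail(roc$tpr, -1)) / 2)
  }
  set.seed(11)
  for (i in 1:25) {
    n <- sample(10:60, 1)
    scores <- sample(round(runif(n), sample(c(1, 2, 6), 1)), n, TRUE)
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) next
    roc <- roc_points(scores, labels)
    expect_lte(abs(trapezoid(roc) - auc(scores, labels)), 1e-12)
    expect_equal(roc$fpr[1], 0); expect_equal(roc$tpr[1], 0)
    expect_equal(roc$fpr[nrow(roc)], 1); expect_equal(roc$tpr[nrow(roc)], 1)
    expect_true(all(diff(roc$fpr) >= 0) && all(diff(roc$tpr) >= 0))
  }
})

test_that("auc and delong agree with pROC", {
  skip_if_not_installed("pROC")
  set.seed(12)
  labels <- rbinom(80, 1, 0.5)
  sa <- rnorm(80) + labels
  sb <- rnorm(80) + 0.5 * labels
  r_a <- pROC::roc(labels, sa, quiet = TRUE, direction = "<")
  expect_equal(auc(sa, labels), as.numeric(pROC::auc(r_a)),
               tolerance = 1e-12)
  r_b <- pROC::roc(labels, sb, quiet = TRUE, direction = "<")
  ref <- pROC::roc.test(r_a, r_b, method = "delong", paired = TRUE)
  mine <- delong_test(sa, sb, labels)
  expect_equal(mine$p_value, ref$p.value, tolerance = 1e-10)
  expect_equal(mine$auc_diff,
               as.numeric(pROC::auc(r_a)) - as.numeric(pROC::auc(r_b)),
               tolerance = 1e-12)
})

test_that("delong handles identical scores and unpaired input", {
  s <- rnorm(30); l <- rbinom(30, 1, 0.5)
  res <- delong_test(s, s, l)
  expect_equal(res$z, 0)
  expect_equal(res$p_value, 1)
  expect_error(delong_test(s[-1], labels = l),
               class = "atnprog_pairing_error")
})

test_that("delong variance matches a bootstrap of the AUC", {
  set.seed(13)
  labels <- rep(c(0, 1), each = 20)
  scores <- rnorm(40) + 0.8 * labels
  v_delong <- delong_test(scores, labels = labels)$se^2
  boot <- replicate(10000, {
    i <- c(sample(which(labels == 0), replace = TRUE),
           sample(which(labels == 1), replace = TRUE))
    auc(scores[i], labels[i])
  })
  expect_lt(abs(var(boot) - v_delong) / v_delong, 0.10)
})

test_that("single-model delong z^2 tracks the Mann-Whitney normal test", {
  set.seed(14)
  scores <- rbinom(200, 1, 0.5)  # two distinct score values
  labels <- rbinom(200, 1, 0.5)
  dl <- delong_test(scores, labels = labels)
  wt <- wilcox.test(scores[labels == 1], scores[labels == 0],
                    correct = FALSE)
  z_mw <- qnorm(wt$p.value / 2) * sign(dl$z) * -1
  expect_lt(abs(dl$z^2 - z_mw^2) / max(z_mw^2, 1e-6), 0.05)
})

test_that("scalar baselines behave at the signal extremes", {
  set.seed(15)
  y <- factor(rep(c("MD", "FD"), each = 30), levels = c("MD", "FD"))
  perfect <- matrix(as.numeric(y == "FD"), ncol = 1)
  sb <- suppressWarnings(scalar_baseline(perfect, y, "logistic", 5, 1))
  expect_equal(sb$accuracy_mean, 1)
  noisef <- matrix(rnorm(60), ncol = 1)
  sbn <- scalar_baseline(noisef, y, "logistic", 5, 1)
  band <- qbinom(c(0.025, 0.975), 60, 0.5) / 60
  expect_gte(sbn$accuracy_mean, band[1] - 0.05)
  expect_lte(sbn$accuracy_mean, band[2] + 0.05)
  svmres <- scalar_baseline(cbind(as.numeric(y == "FD"), rnorm(60)), y,
                            "svm_rbf", 5, 1)
  expect_gte(svmres$accuracy_mean, 0.9)
  w <- testthat::capture_warnings(
    scalar_baseline(cbind(rnorm(60), rep(1, 60)), y, "logistic", 5, 1))
  expect_true(any(grepl("constant", w)))  # warned once per affected fold
})

test_that("the ablation harness is pure: identical runs give identical metrics", {
  coh <- tiny_cohort(n = 20, volumes = TRUE)
  spec <- penet_spec(input_shape = c(8, 8, 8), conv_filters = c(2, 3),
                     sepconv_filters = c(4, 5, 6), conv_strides = c(2, 2),
                     sepconv_strides = c(1, 2, 1),
                     scalar_branch_widths = c(4, 2), fusion_widths = c(8, 4))
  cfg <- desk_train_config(epochs = 2, folds = 3, seed = 21)
  a1 <- run_ablation(coh, "n", spec, cfg)
  a2 <- run_ablation(coh, "n", spec, cfg)
  expect_identical(a1$results$n$accuracy_mean, a2$results$n$accuracy_mean)
  expect_identical(a1$results$n$oof$prob_fd, a2$results$n$oof$prob_fd)
  # identical fold index sets across combinations (paired design)
  a3 <- run_ablation(coh, c("n", "mri_only"), spec, cfg)
  expect_identical(a3$folds, a1$folds)
  expect_error(run_ablation(coh, "banana", spec, cfg),
               class = "atnprog_config_error")
})

test_that("redundancy analysis reports both directions and error contracts", {
  coh <- tiny_cohort(n = 40, seed = 17)
  set.seed(18)
  pred_an <- factor(sample(c("MD", "FD"), 40, TRUE), levels = c("MD", "FD"))
  pred_tn <- factor(sample(c("MD", "FD"), 40, TRUE), levels = c("MD", "FD"))
  ra <- redundancy_analysis(coh, pred_an, pred_tn)
  expect_named(ra, c("ptau_by_an_groups", "abeta_by_tn_groups"))
  expect_true(ra$ptau_by_an_groups$p_value >= 0 &
                ra$ptau_by_an_groups$p_value <= 1)
  # degenerate: an empty predicted group
  allfd <- factor(rep("FD", 40), levels = c("MD", "FD"))
  expect_error(redundancy_analysis(coh, allfd, pred_tn),
               class = "atnprog_degenerate_group_error")
})

test_that("combination labels map to the documented modality sets", {
  cm <- atnprog:::combination_modalities
  expect_identical(cm("n"), c("mri", "fdg"))
  expect_identical(cm("an"), c("mri", "fdg", "abeta"))
  expect_identical(cm("tn"), c("mri", "fdg", "ptau"))
  expect_identical(cm("atn"), c("mri", "fdg", "abeta", "ptau"))
  expect_identical(cm("n_icv"), c("mri", "fdg", "icv"))
  expect_identical(cm("mri_only"), "mri")
  expect_identical(cm("n_noise"), c("mri", "fdg", "noise"))
})

test_that("svm imaging features have the documented layout", {
  coh <- tiny_cohort(n = 6, volumes = TRUE, shape = c(16, 16, 16))
  X <- svm_imaging_features(coh, grid = 4L)
  expect_equal(dim(X), c(6L, 4^3 + 1L))
  expect_equal(unname(X[, ncol(X)]), coh$biomarkers$fdg)
})

test_that("combination comparison pairs scores and supports adjustment", {
  coh <- tiny_cohort(n = 20, volumes = TRUE)
  spec <- penet_spec(input_shape = c(8, 8, 8), conv_filters = c(2, 3),
                     sepconv_filters = c(4, 5, 6), conv_strides = c(2, 2),
                     sepconv_strides = c(1, 2, 1),
                     scalar_branch_widths = c(4, 2), fusion_widths = c(8, 4))
  ab <- run_ablation(coh, c("n", "tn", "atn"), spec,
                     desk_train_config(epochs = 1, folds = 2))
  cmp <- compare_combinations(ab, reference = "n")
  expect_equal(cmp$combination, c("tn", "atn"))
  expect_true(all(cmp$p_value >= 0 & cmp$p_value <= 1))
  cmph <- compare_combinations(ab, reference = "n", adjust = "holm")
  expect_true(all(cmph$p_value >= cmp$p_value - 1e-12))
  expect_error(compare_combinations(ab, reference = "x"),
               class = "atnprog_config_error")
})
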