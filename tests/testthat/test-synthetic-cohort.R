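test_that("same config and seed give a bitwise-identical cohort", {
  cfg <- cohort_config(n_subjects = 12, seed = 7, volume_shape = c(8, 8, 8))
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))
  cfg2 <- cohort_config(n_subjects = 12, seed = 8, volume_shape = c(8, 8, 8))
  expect_false(identical(generate_cohort(cfg)$trajectories$scores,
                         generate_cohort(cfg2)$trajectories$scores))
})

test_that("noise-free linear trajectories decline exactly by slope x years", {
  coh <- generate_cohort(noisefree_config(n = 20))
  sc <- coh$trajectories$scores
  drop24 <- sc[, 4] - sc[, 1]
  expect_equal(unname(drop24[coh$true_class == "MD"]),
               rep(-2, sum(coh$true_class == "MD")))
  expect_equal(unname(drop24[coh$true_class == "FD"]),
               rep(-8, sum(coh$true_class == "FD")))
  # every FD trajectory lies strictly below its baseline after baseline
  fd <- sc[coh$true_class == "FD", , drop = FALSE]
  expect_true(all(fd[, 2:4] < fd[, 1]))
})

test_that("class counts match requested proportions within one subject", {
  for (n in c(21, 50, 101)) {
    coh <- generate_cohort(cohort_config(n_subjects = n, seed = n,
                                         generate_volumes = FALSE))
    expect_lte(abs(sum(coh$true_class == "MD") - 0.6 * n), 1)
  }
})

test_that("per-subject containers share ordering and physical invariants", {
  coh <- tiny_cohort(n = 30, volumes = TRUE)
  expect_identical(coh$biomarkers$subject_id, coh$subject_ids)
  expect_identical(coh$regional_volumes$subject_id, coh$subject_ids)
  expect_true(all(coh$regional_volumes$hippocampal_volume <
                    coh$regional_volumes$cortical_total_volume))
  expect_true(all(coh$biomarkers$abeta > 0 & coh$biomarkers$ptau > 0 &
                    coh$biomarkers$icv > 0))
  expect_true(all(vapply(coh$volumes,
                         function(v) identical(dim(v), c(8L, 8L, 8L)),
                         logical(1))))
})

test_that("synergy mode recovers the interaction coefficient by logistic refit", {
  coh <- generate_cohort(synergy_cohort_config(n_subjects = 2000, seed = 11,
                                               generate_volumes = FALSE))
  fit <- glm(coh$true_class ~ z_a * z_t + z_n, data = coh$latents,
             family = binomial())
  est <- summary(fit)$coefficients["z_a:z_t", ]
  ci <- est["Estimate"] + c(-1, 1) * 1.96 * est["Std. Error"]
  expect_gt(2, ci[1])
  expect_lt(2, ci[2])
})

test_that("invalid configurations raise classed configuration errors", {
  expect_error(cohort_config(n_subjects = 3), class = "atnprog_cohort_size_error")
  expect_error(cohort_config(visit_months = c(0, 6, 6, 24)),
               class = "atnprog_config_error")
  expect_error(cohort_config(volume_shape = c(4, 8, 8)),
               class = "atnprog_config_error")
  expect_error(cohort_config(class_proportions = c(MD = 0.7, FD = 0.4)),
               class = "atnprog_config_error")
  bad <- cohort_config(n_subjects = 10)
  bad$trajectory_params$MD$slope_mean <- NaN
  expect_error(generate_cohort(bad), class = "atnprog_config_error")
})

test_that("inclusion filter applies strict cutoffs with CSF precedence", {
  bm <- data.frame(subject_id = paste0("S", 1:5),
                   abeta = c(900, 1000, 950, 1200, NA),
                   suvr = c(NA, 1.2, 1.3, 1.0, 1.5))
  f <- apply_inclusion_filter(bm)
  expect_setequal(f$included, c("S1", "S2", "S3", "S5"))
  expect_equal(f$counts$csf, 2)
  expect_equal(f$counts$pet_only, 2)
  # boundary values are excluded under strict inequalities
  b2 <- apply_inclusion_filter(data.frame(subject_id = "X", abeta = 1000,
                                          suvr = 1.11))
  expect_length(b2$included, 0)
  expect_equal(b2$table$reason, "amyloid-negative")
  # single CSF qualifier
  b3 <- apply_inclusion_filter(data.frame(subject_id = "Y", abeta = 900,
                                          suvr = NA))
  expect_equal(b3$table$reason, "csf")
  # both measures missing
  b4 <- apply_inclusion_filter(data.frame(subject_id = "Z", abeta = NA,
                                          suvr = NA))
  expect_equal(b4$table$reason, "no amyloid measure")
  expect_equal(b4$counts$no_measure, 1)
})

test_that("inclusion filter is idempotent and order-independent", {
  coh <- tiny_cohort(n = 40, seed = 5)
  f1 <- apply_inclusion_filter(coh$biomarkers)
  again <- apply_inclusion_filter(
    coh$biomarkers[coh$biomarkers$subject_id %in% f1$included, ])
  expect_setequal(again$included, f1$included)
  shuf <- coh$biomarkers[sample(nrow(coh$biomarkers)), ]
  f2 <- apply_inclusion_filter(shuf)
  expect_setequal(f2$included, f1$included)
})
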