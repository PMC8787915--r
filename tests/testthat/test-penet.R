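small_spec <- function(...) {
  penet_spec(input_shape = c(8, 8, 8), conv_filters = c(2, 3),
             sepconv_filters = c(4, 5, 6), conv_strides = c(2, 2),
             sepconv_strides = c(1, 2, 1), scalar_branch_widths = c(4, 2),
             fusion_widths = c(8, 4), ...)
}

test_that("output probabilities are a valid softmax over 2 classes", {
  spec <- small_spec(enabled_modalities = c("mri", "fdg", "ptau"))
  model <- build_penet(spec, seed = 2)
  set.seed(1)
  batch <- list(vols = array(rnorm(8^3 * 3), c(8, 8, 8, 1, 3)),
                scalars = list(fdg = rnorm(3), ptau = rnorm(3)))
  p <- predict(model, batch)
  expect_equal(dim(p), c(3L, 2L))
  expect_true(all(p >= 0 & p <= 1))
  expect_equal(rowSums(p), rep(1, 3), tolerance = 1e-6)
})

test_that("separable blocks cost strictly fewer parameters than full convs", {
  for (k in c(3, 5)) for (cin in c(4, 8)) for (cout in c(8, 16)) {
    conv_params <- k^3 * cin * cout + cout
    sep_params <- k^3 * cin + cin * cout + cout
    expect_lt(sep_params, conv_params)
  }
})

test_that("model parameter count matches the closed form, per modality", {
  count_params <- function(model) {
    tot <- 0
    for (L in model$vol_layers) {
      tot <- tot + length(L$bn$gamma) + length(L$bn$beta)
      tot <- tot + if (L$type == "conv") length(L$W) + length(L$b) else
        length(L$Wd) + length(L$Wp) + length(L$bp)
    }
    for (br in model$branches)
      for (L in br) tot <- tot + length(L$W) + length(L$b)
    for (L in model$fusion) tot <- tot + length(L$W) + length(L$b)
    tot
  }
  spec_full <- small_spec(enabled_modalities = c("mri", "fdg", "ptau"))
  spec_red <- small_spec(enabled_modalities = c("mri", "fdg"))
  expect_equal(count_params(build_penet(spec_full)),
               penet_param_count(spec_full)$total)
  expect_equal(count_params(build_penet(spec_red)),
               penet_param_count(spec_red)$total)
  # disabling a scalar modality removes exactly that branch's parameters
  # plus its share of the first fusion layer
  pc_full <- penet_param_count(spec_full)
  pc_red <- penet_param_count(spec_red)
  w_last <- spec_full$scalar_branch_widths[2]
  fusion_share <- w_last * spec_full$fusion_widths[1]
  expect_equal(pc_full$total - pc_red$total,
               pc_full$branches$ptau + fusion_share)
})

test_that("spec invariants are enforced", {
  expect_error(penet_spec(conv_filters = c(8, 16, 32)),
               class = "atnprog_config_error")
  expect_error(penet_spec(conv_filters = c(16, 8)),
               class = "atnprog_config_error")
  expect_error(penet_spec(sepconv_filters = c(16, 16, 32)),
               class = "atnprog_config_error")
  expect_error(penet_spec(enabled_modalities = "pet"),
               class = "atnprog_config_error")
  expect_error(penet_spec(kernel_size = 2), class = "atnprog_config_error")
})

test_that("enabled modality missing from the data raises a modality error", {
  coh <- tiny_cohort(n = 10, volumes = FALSE)
  spec <- small_spec(enabled_modalities = c("mri", "fdg"))
  expect_error(atnprog:::penet_data(coh, spec),
               class = "atnprog_modality_error")
  spec2 <- small_spec(enabled_modalities = c("fdg", "noise"))
  expect_error(atnprog:::penet_data(coh, spec2),
               class = "atnprog_modality_error")
})

test_that("standardize_inputs z-scores with training statistics only", {
  set.seed(5)
  tr <- list(scalars = data.frame(a = rnorm(30, 5, 2), b = runif(30)))
  te <- list(scalars = data.frame(a = rnorm(10, 9, 2), b = runif(10)))
  out <- standardize_inputs(tr, te)
  expect_equal(mean(out$train$scalars$a), 0, tolerance = 1e-10)
  expect_equal(sd(out$train$scalars$a), 1, tolerance = 1e-10)
  # held-out features standardized with training stats: mean != 0 in general
  expect_gt(abs(mean(out$apply$scalars$a)), 0.5)
  # re-applying a transform is guarded
  expect_error(standardize_inputs(out$train),
               class = "atnprog_transform_error")
  # zero-variance feature dropped with a warning
  trz <- list(scalars = data.frame(a = rnorm(10), z = rep(3, 10)))
  expect_warning(outz <- standardize_inputs(trz), "zero-variance")
  expect_named(outz$train$scalars, "a")
  expect_identical(outz$transform$dropped, "z")
})

test_that("volumes are standardized per image", {
  set.seed(6)
  a <- array(rnorm(4^3 * 3, 7, 3), c(4, 4, 4, 1, 3))
  z <- atnprog:::zvol_array(a)
  for (i in 1:3) {
    expect_equal(mean(z[, , , , i]), 0, tolerance = 1e-10)
    expect_equal(sd(as.numeric(z[, , , , i])) *
                   sqrt((4^3 - 1) / 4^3), 1, tolerance = 1e-10)
  }
})

test_that("stratified folds balance classes within one subject", {
  lab <- rep(c("MD", "FD"), c(60, 40))
  f <- stratified_folds(lab, 5, seed = 3)
  expect_equal(sort(unlist(f)), 1:100)
  for (fold in f) {
    expect_equal(sum(lab[fold] == "MD"), 12)
    expect_equal(sum(lab[fold] == "FD"), 8)
  }
  # 97 subjects, 58/39: per-fold class counts within +/-1 of n_c / k
  lab2 <- rep(c("MD", "FD"), c(58, 39))
  f2 <- stratified_folds(lab2, 5, seed = 4)
  expect_equal(sort(unlist(f2)), 1:97)
  for (fold in f2) {
    expect_lte(abs(sum(lab2[fold] == "MD") - 58 / 5), 1)
    expect_lte(abs(sum(lab2[fold] == "FD") - 39 / 5), 1)
  }
  expect_identical(f, stratified_folds(lab, 5, seed = 3))
  expect_error(stratified_folds(rep(c("a", "b"), c(3, 50)), 5, 1),
               class = "atnprog_stratification_error")
})

test_that("augmentation identities hold and degenerate axes error", {
  set.seed(7)
  v <- array(rnorm(6^3), c(6, 6, 6))
  id_settings <- augment_settings(rotation_range = c(0, 0),
                                  translation_range = c(0, 0),
                                  flip_axes = integer(0))
  expect_identical(augment_volume(v, id_settings, seed = 1), v)
  expect_identical(atnprog:::flip_volume(atnprog:::flip_volume(v, 2), 2), v)
  expect_error(atnprog:::rotate_axial(array(1, c(1, 5, 5)), 30, 0, "nearest"),
               class = "atnprog_axis_error")
})

test_that("small shifts keep the mean intensity of phantoms within 5%", {
  coh <- tiny_cohort(n = 4, volumes = TRUE, shape = c(16, 16, 16))
  st <- augment_settings(rotation_range = c(0, 0),
                         translation_range = c(0.1, 0.1),
                         flip_axes = integer(0))
  for (i in 1:4) {
    v <- coh$volumes[[i]]
    av <- augment_volume(v, st, seed = i)
    expect_identical(dim(av), dim(v))
    expect_lt(abs(mean(av) - mean(v)) / abs(mean(v)), 0.05)
  }
})

test_that("trilinear resampling preserves constants and identity shapes", {
  v <- array(5, c(8, 8, 8))
  expect_equal(resample_volume(v, c(4, 4, 4)), array(5, c(4, 4, 4)))
  w <- array(rnorm(8^3), c(8, 8, 8))
  expect_identical(resample_volume(w, c(8, 8, 8)), w)
  # nearest-neighbour at identical shape is also exact
  expect_identical(resample_volume(w, c(8, 8, 8), "nearest"), w)
})
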