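#' Architecture specification for the parameter-efficient network (PENet)
#'
#' PENet encodes a 3D volume with 2 convolution blocks followed by 3
#' depthwise-separable convolution blocks with strictly increasing filter
#' counts (each block: convolution, batch normalisation, ELU), passes each
#' enabled scalar biomarker through its own small fully-connected branch,
#' concatenates all features and classifies through fully-connected fusion
#' layers ending in a 2-class softmax. Separable blocks use a depthwise
#' convolution followed by a pointwise (1x1x1) convolution, which costs far
#' fewer parameters than a full convolution with the same filter count.
#'
#' @param input_shape 3 integers: volume shape fed to the encoder (inputs of
#'   other shapes are resampled trilinearly).
#' @param conv_filters 2 filter counts for the conv blocks.
#' @param conv_strides strides for the conv blocks.
#' @param sepconv_filters 3 filter counts for the sep-conv blocks.
#' @param sepconv_strides strides for the sep-conv blocks.
#' @param kernel_size odd kernel size shared by all spatial convolutions.
#' @param scalar_branch_widths fully-connected widths of each scalar branch.
#' @param fusion_widths fully-connected widths of the fusion head (a final
#'   2-unit softmax layer is appended automatically).
#' @param dropout dropout probability on fusion activations during training.
#' @param enabled_modalities subset of `"mri"`, `"fdg"`, `"abeta"`, `"ptau"`,
#'   `"icv"`, `"noise"`; `"mri"` enables the volume encoder, the others are
#'   scalar branches.
#' @return object of class `penet_spec`.
#' @export
penet_spec <- function(input_shape = c(16, 16, 16),
                       conv_filters = c(8, 16),
                       conv_strides = c(2, 2),
                       sepconv_filters = c(24, 32, 48),
                       sepconv_strides = c(2, 1, 2),
                       kernel_size = 3,
                       scalar_branch_widths = c(8, 4),
                       fusion_widths = c(32, 16),
                       dropout = 0,
                       enabled_modalities = c("mri", "fdg", "ptau", "abeta")) {
  spec <- structure(
    list(input_shape = as.integer(input_shape),
         conv_filters = as.integer(conv_filters),
         conv_strides = as.integer(conv_strides),
         sepconv_filters = as.integer(sepconv_filters),
         sepconv_strides = as.integer(sepconv_strides),
         kernel_size = as.integer(kernel_size),
         scalar_branch_widths = as.integer(scalar_branch_widths),
         fusion_widths = as.integer(fusion_widths),
         dropout = dropout,
         enabled_modalities = enabled_modalities),
    class = "penet_spec")
  validate_penet_spec(spec)
  spec
}

validate_penet_spec <- function(spec) {
  if (length(spec$conv_filters) != 2L || length(spec$sepconv_filters) != 3L)
    abort("PENet uses exactly 2 conv blocks followed by 3 sep-conv blocks",
          "atnprog_config_error")
  filters <- c(spec$conv_filters, spec$sepconv_filters)
  if (any(diff(filters) <= 0))
    abort("filter counts must be strictly increasing across the 5 blocks",
          "atnprog_config_error")
  if (spec$kernel_size %% 2L != 1L || spec$kernel_size < 1L)
    abort("kernel size must be odd and positive", "atnprog_config_error")
  if (length(spec$input_shape) != 3L || any(spec$input_shape < 4L))
    abort("input_shape must be 3 integers, each >= 4", "atnprog_config_error")
  if (spec$dropout < 0 || spec$dropout >= 1)
    abort("dropout must lie in [0, 1)", "atnprog_config_error")
  known <- c("mri", "fdg", "abeta", "ptau", "icv", "noise")
  if (!length(spec$enabled_modalities) ||
      !all(spec$enabled_modalities %in% known))
    abort(sprintf("enabled_modalities must be a non-empty subset of {%s}",
                  paste(known, collapse = ", ")), "atnprog_config_error")
  spat <- penet_block_shapes(spec)
  if (any(unlist(spat) < 1L))
    abort("input_shape too small for the configured strides",
          "atnprog_config_error")
  invisible(spec)
}

# Spatial shape after each of the 5 blocks (padded "same"-style convolution:
# pad = (k - 1) / 2, out = floor((n + 2p - k) / s) + 1).
penet_block_shapes <- function(spec) {
  k <- spec$kernel_size
  p <- (k - 1L) %/% 2L
  shp <- spec$input_shape
  strides <- c(spec$conv_strides, spec$sepconv_strides)
  lapply(strides, function(s) {
    shp <<- (shp + 2L * p - k) %/% s + 1L
    shp
  })
}

#' Compact desk-scale PENet specification
#'
#' A reduced preset of [penet_spec()] sized for single-CPU experiments on
#' 32^3 phantom volumes (resampled to 16^3 at the encoder input): filters
#' 4/8 for the conv blocks and 12/16/24 for the sep-conv blocks.
#'
#' @param enabled_modalities passed to [penet_spec()].
#' @param ... further overrides for [penet_spec()].
#' @return a `penet_spec`.
#' @export
desk_penet_spec <- function(enabled_modalities = c("mri", "fdg", "ptau",
                                                   "abeta"), ...) {
  penet_spec(conv_filters = c(4, 8), sepconv_filters = c(12, 16, 24),
             fusion_widths = c(16, 8),
             enabled_modalities = enabled_modalities, ...)
}

#' Closed-form parameter count of a PENet specification
#'
#' Counts learnable parameters per component: full convolutions cost
#' \eqn{k^3 C_{in} C_{out} + C_{out}} (+ 2 batch-norm parameters per
#' channel), separable convolutions \eqn{k^3 C_{in} + C_{in} C_{out} +
#' C_{out}} (+ batch norm), fully-connected layers `in * out + out`.
#'
#' @param spec a [penet_spec()].
#' @return list with `total` and a per-component breakdown (`volume`,
#'   `branches` named per modality, `fusion`).
#' @export
penet_param_count <- function(spec) {
  k3 <- spec$kernel_size^3
  vol <- 0L
  scalar_mods <- setdiff(spec$enabled_modalities, "mri")
  feat_dim <- 0L
  if ("mri" %in% spec$enabled_modalities) {
    cin <- 1L
    for (f in spec$conv_filters) {
      vol <- vol + k3 * cin * f + f + 2L * f
      cin <- f
    }
    for (f in spec$sepconv_filters) {
      vol <- vol + k3 * cin + cin * f + f + 2L * f
      cin <- f
    }
    shapes <- penet_block_shapes(spec)
    feat_dim <- prod(shapes[[5L]]) * cin
  }
  branch_one <- {
    widths <- spec$scalar_branch_widths
    sum((c(1L, head(widths, -1L)) * widths) + widths)
  }
  branches <- setNames(rep(branch_one, length(scalar_mods)), scalar_mods)
  fusion_in <- feat_dim + length(scalar_mods) *
    spec$scalar_branch_widths[length(spec$scalar_branch_widths)]
  widths <- c(spec$fusion_widths, 2L)
  fusion <- sum((c(fusion_in, head(widths, -1L)) * widths) + widths)
  list(total = vol + sum(branches) + fusion,
       volume = vol, branches = as.list(branches), fusion = fusion)
}

#' Training configuration for PENet
#'
#' Defaults follow the reference training regime: stochastic gradient
#' descent, batch size 25, 50 epochs, initial learning rate 8e-4 with
#' exponential decay (rate 0.5 every `lr_decay_period` epochs), L2 penalty
#' 5e-4 on fully-connected weights, and 5-fold stratified cross-validation.
#'
#' @param batch_size minibatch size.
#' @param epochs training epochs.
#' @param learning_rate initial SGD learning rate.
#' @param lr_decay_rate multiplicative drop applied every decay period.
#' @param lr_decay_period epochs between learning-rate drops.
#' @param l2_fc L2 penalty coefficient on fully-connected weights.
#' @param folds number of cross-validation folds.
#' @param augment_copies augmented copies per training subject (0 disables
#'   augmentation).
#' @param augment settings from [augment_settings()].
#' @param seed integer seed controlling weight init, shuffling, augmentation
#'   and fold assignment.
#' @return object of class `train_config`.
#' @export
train_config <- function(batch_size = 25, epochs = 50, learning_rate = 8e-4,
                         lr_decay_rate = 0.5, lr_decay_period = 10,
                         l2_fc = 5e-4, folds = 5, augment_copies = 2,
                         augment = augment_settings(), seed = 1L) {
  stopifnot(batch_size >= 1, epochs >= 1, learning_rate > 0,
            lr_decay_rate > 0, lr_decay_period >= 1, l2_fc >= 0, folds >= 2,
            augment_copies >= 0)
  structure(list(batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 learning_rate = learning_rate,
                 lr_decay_rate = lr_decay_rate,
                 lr_decay_period = as.integer(lr_decay_period),
                 l2_fc = l2_fc, folds = as.integer(folds),
                 augment_copies = as.integer(augment_copies),
                 augment = augment, seed = as.integer(seed)),
            class = "train_config")
}

#' Desk-scale training configuration
#'
#' Preset for single-CPU experiments: 10 epochs, learning rate 0.1 (the
#' handful of SGD updates available at desk scale needs a larger step than
#' the GPU-scale default), decay period 4, no augmentation copies; batch
#' size, decay rate, L2 penalty and fold count keep their defaults.
#'
#' @param epochs,learning_rate,augment_copies,seed overrides.
#' @param ... further overrides for [train_config()].
#' @return a `train_config`.
#' @export
desk_train_config <- function(epochs = 10, learning_rate = 0.1,
                              augment_copies = 0, seed = 1L, ...) {
  train_config(epochs = epochs, learning_rate = learning_rate,
               lr_decay_period = 4, augment_copies = augment_copies,
               seed = seed, ...)
}

#' Settings for random 3D volume augmentation
#'
#' @param rotation_range rotation angle range in degrees (axial plane).
#' @param translation_range random shift range as a fraction of each
#'   dimension.
#' @param flip_axes axes eligible for random flips (empty to disable).
#' @param fill background fill value for voxels leaving the field of view.
#' @param interpolation `"nearest"` (default; exact identity at angle 0) or
#'   `"trilinear"`.
#' @return list of class `augment_settings`.
#' @export
augment_settings <- function(rotation_range = c(-90, 90),
                             translation_range = c(0, 0.5),
                             flip_axes = 1L, fill = 0,
                             interpolation = c("nearest", "trilinear")) {
  stopifnot(length(rotation_range) == 2L, diff(rotation_range) >= 0,
            length(translation_range) == 2L, all(translation_range >= 0),
            all(translation_range <= 1))
  structure(list(rotation_range = rotation_range,
                 translation_range = translation_range,
                 flip_axes = as.integer(flip_axes), fill = fill,
                 interpolation = match.arg(interpolation)),
            class = "augment_settings")
}
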