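#' Standardise model inputs with training-fold statistics
#'
#' Volumes are z-scored per image (zero mean, unit sd within each volume),
#' which needs no training statistics. Scalar features are z-scored per
#' feature using the *training* rows only; the same transform is then
#' applied to the `apply` rows, so no information leaks from held-out
#' subjects. Zero-variance training features are dropped with a warning.
#' A `standardized` attribute guards against accidentally applying the
#' transform twice.
#'
#' @param train list with optional `vols` (list of 3D arrays or a 5-D
#'   array) and `scalars` (data frame / named list of numeric vectors).
#' @param apply optional list in the same layout to transform with the
#'   training statistics.
#' @return list with `train`, `apply` (or `NULL`) and `transform` (centers,
#'   scales, dropped feature names).
#' @export
standardize_inputs <- function(train, apply = NULL) {
  if (isTRUE(attr(train, "standardized")))
    abort("inputs are already standardized", "atnprog_transform_error")
  zvol <- function(v) { s <- sd(v); if (s == 0) v * 0 else (v - mean(v)) / s }
  std_vols <- function(vl) {
    if (is.null(vl)) return(NULL)
    if (is.list(vl)) lapply(vl, zvol) else zvol_array(vl)
  }
  ctr <- scl <- NULL
  dropped <- character(0)
  if (!is.null(train$scalars)) {
    sc <- as.data.frame(train$scalars)
    ctr <- vapply(sc, mean, numeric(1))
    scl <- vapply(sc, sd, numeric(1))
    bad <- !is.finite(scl) | scl == 0
    if (any(bad)) {
      warning(sprintf("dropping zero-variance feature(s): %s",
                      paste(names(sc)[bad], collapse = ", ")))
      dropped <- names(sc)[bad]
      sc <- sc[!bad]
      ctr <- ctr[!bad]; scl <- scl[!bad]
    }
    train$scalars <- as.data.frame(mapply(function(v, m, s) (v - m) / s,
                                          sc, ctr, scl, SIMPLIFY = FALSE))
  }
  train$vols <- std_vols(train$vols)
  attr(train, "standardized") <- TRUE
  if (!is.null(apply)) {
    if (isTRUE(attr(apply, "standardized")))
      abort("inputs are already standardized", "atnprog_transform_error")
    if (!is.null(apply$scalars)) {
      sc <- as.data.frame(apply$scalars)
      sc <- sc[setdiff(names(sc), dropped)]
      apply$scalars <- as.data.frame(mapply(function(v, m, s) (v - m) / s,
                                            sc, ctr[names(sc)],
                                            scl[names(sc)],
                                            SIMPLIFY = FALSE))
    }
    apply$vols <- std_vols(apply$vols)
    attr(apply, "standardized") <- TRUE
  }
  list(train = train, apply = apply,
       transform = list(center = ctr, scale = scl, dropped = dropped))
}

# z-score each volume of a (D,H,W,1,N) array independently.
zvol_array <- function(a) {
  d <- dim(a)
  n <- d[5L]
  m <- matrix(a, ncol = n)
  mu <- colMeans(m)
  s <- sqrt(colMeans(m^2) - mu^2)
  s[s == 0] <- 1
  array(sweep(sweep(m, 2L, mu), 2L, s, `/`), d)
}

#' Stratified cross-validation folds
#'
#' Partitions subject indices into `k` disjoint folds, stratified so each
#' fold's class proportions match the global proportions within one
#' subject per class. Deterministic given the seed.
#'
#' @param labels class labels.
#' @param k number of folds.
#' @param seed integer seed.
#' @return list of `k` integer index vectors (a partition of
#'   `seq_along(labels)`).
#' @export
stratified_folds <- function(labels, k, seed = 1L) {
  labels <- as.factor(labels)
  k <- as.integer(k)
  if (any(table(labels) < k))
    abort("every class needs at least k members for k folds",
          "atnprog_stratification_error")
  withr::with_seed(seed, {
    folds <- vector("list", k)
    for (ci in seq_len(nlevels(labels))) {
      idx <- sample(which(labels == levels(labels)[ci]))
      # snake the fold order across classes to even out fold sizes
      ford <- if (ci %% 2L == 1L) seq_len(k) else rev(seq_len(k))
      bins <- rep(ford, length.out = length(idx))
      for (f in seq_len(k))
        folds[[f]] <- c(folds[[f]], idx[bins == f])
    }
    lapply(folds, sort)
  })
}

validate_folds <- function(folds, n) {
  all_idx <- sort(unlist(folds))
  if (length(all_idx) != n || !identical(all_idx, seq_len(n)))
    abort("folds must partition all subject indices",
          "atnprog_leakage_error")
  for (f in seq_along(folds))
    for (g in seq_along(folds))
      if (f < g && length(intersect(folds[[f]], folds[[g]])))
        abort("folds overlap: a test subject appears in the training pool",
              "atnprog_leakage_error")
  invisible(TRUE)
}

# Build the model-facing data bundle for a subject subset.
penet_data <- function(cohort, spec, indices = NULL, extra_scalars = NULL) {
  indices <- indices %||% seq_along(cohort$subject_ids)
  scalar_mods <- setdiff(spec$enabled_modalities, "mri")
  vols <- NULL
  if ("mri" %in% spec$enabled_modalities) {
    if (is.null(cohort$volumes))
      abort("modality 'mri' enabled but cohort has no volumes",
            "atnprog_modality_error")
    shp <- spec$input_shape
    vols <- array(0, c(shp, 1L, length(indices)))
    for (i in seq_along(indices))
      vols[, , , 1L, i] <- resample_volume(cohort$volumes[[indices[i]]], shp)
  }
  scalars <- list()
  for (m in scalar_mods) {
    v <- if (!is.null(extra_scalars) && m %in% names(extra_scalars))
      extra_scalars[[m]][indices] else cohort$biomarkers[[m]][indices]
    if (is.null(v) || anyNA(v))
      abort(sprintf("modality '%s' enabled but missing from the data", m),
            "atnprog_modality_error")
    scalars[[m]] <- v
  }
  list(vols = vols, scalars = scalars,
       subject_ids = cohort$subject_ids[indices])
}

#' Train a PENet on a fixed training set
#'
#' Minibatch stochastic gradient descent with exponential learning-rate
#' decay and L2 regularisation on fully-connected weights. All randomness
#' (shuffling, dropout) is driven by the configured seed; single-threaded
#' execution makes runs bit-reproducible.
#'
#' @param model a `penet_model` from [build_penet()].
#' @param data list with `vols` ((D,H,W,1,N) standardised array or NULL),
#'   `scalars` (named list of standardised vectors) and `y` (factor MD/FD
#'   or 0/1 with 1 = FD).
#' @param config a [train_config()].
#' @return the trained model (with `loss_history` attached).
#' @export
train_penet <- function(model, data, config) {
  y <- if (is.factor(data$y)) as.integer(data$y == "FD") else
    as.integer(data$y)
  n <- length(y)
  onehot <- cbind(1 - y, y)
  withr::with_seed(config$seed, {
    losses <- numeric(config$epochs)
    for (ep in seq_len(config$epochs)) {
      lr <- config$learning_rate *
        config$lr_decay_rate^((ep - 1) %/% config$lr_decay_period)
      ord <- sample.int(n)
      starts <- seq(1L, n, by = config$batch_size)
      ep_loss <- 0
      for (s in starts) {
        idx <- ord[s:min(s + config$batch_size - 1L, n)]
        batch <- list(
          vols = if (!is.null(data$vols)) data$vols[, , , , idx, drop = FALSE],
          scalars = lapply(data$scalars, `[`, idx))
        fw <- penet_forward(model, batch, training = TRUE)
        model <- fw$model
        # raw (unclamped) probabilities so a collapsed softmax surfaces as
        # a non-finite loss instead of silently saturating
        loss <- -mean(log(fw$probs[cbind(seq_along(idx), y[idx] + 1L)]))
        if (!is.finite(loss))
          abort(sprintf(
            "training diverged (NaN loss) at epoch %d; lr = %g, seed = %d",
            ep, lr, config$seed), "atnprog_divergence_error")
        ep_loss <- ep_loss + loss * length(idx)
        grads <- penet_backward(model, fw$caches, fw$probs,
                                onehot[idx, , drop = FALSE])
        model <- penet_sgd_step(model, grads, lr, config$l2_fc)
      }
      losses[ep] <- ep_loss / n
    }
    model$trained <- TRUE
    model$loss_history <- losses
    model
  })
}

#' Stratified cross-validated PENet training
#'
#' For each fold: training subjects are augmented (configured copies per
#' subject, training pool only), inputs are standardised with training-fold
#' statistics, the model is trained from scratch and evaluated on the
#' untouched held-out fold. A leakage guard asserts every fold that the set
#' of subject ids contributing any tensor to fitting is disjoint from the
#' evaluation fold.
#'
#' @param cohort an `atn_cohort` (or compatible list).
#' @param spec a [penet_spec()].
#' @param config a [train_config()].
#' @param labels per-subject class labels (factor MD/FD); defaults to the
#'   cohort's `true_class`.
#' @param folds optional precomputed fold index sets (validated); defaults
#'   to [stratified_folds()] under the config seed.
#' @param extra_scalars named list of per-subject scalar vectors overriding
#'   or extending the cohort biomarkers (used e.g. for noise probes).
#' @return object of class `penet_cv`: per-fold results, pooled out-of-fold
#'   predictions, and a summary with fold-accuracy mean/sd, pooled accuracy
#'   and pooled AUC.
#' @export
train_cv <- function(cohort, spec, config, labels = cohort$true_class,
                     folds = NULL, extra_scalars = NULL) {
  labels <- as.factor(labels)
  n <- length(labels)
  folds <- folds %||% stratified_folds(labels, config$folds, config$seed)
  validate_folds(folds, n)
  oof_prob <- rep(NA_real_, n)
  fold_results <- vector("list", length(folds))

  for (f in seq_along(folds)) {
    test_idx <- folds[[f]]
    train_idx <- setdiff(seq_len(n), test_idx)
    # leakage guard: ids feeding the fit must be disjoint from the fold
    if (length(intersect(train_idx, test_idx)))
      abort("leakage: training pool intersects evaluation fold",
            "atnprog_leakage_error")
    tr <- penet_data(cohort, spec, train_idx, extra_scalars)
    te <- penet_data(cohort, spec, test_idx, extra_scalars)
    y_tr <- labels[train_idx]
    if (config$augment_copies > 0L && !is.null(tr$vols)) {
      aug <- augment_training_volumes(tr, y_tr, config,
                                      seed = derive_seed(config$seed,
                                                         paste0("aug", f)))
      tr <- aug$data
      y_tr <- aug$y
      if (length(intersect(aug$source_ids, te$subject_ids)))
        abort("leakage: augmented copy of a test subject entered training",
              "atnprog_leakage_error")
    }
    std <- standardize_inputs(list(vols = tr$vols, scalars = tr$scalars),
                              list(vols = te$vols, scalars = te$scalars))
    model <- build_penet(spec, seed = derive_seed(config$seed,
                                                  paste0("init", f)))
    fold_cfg <- config
    fold_cfg$seed <- derive_seed(config$seed, paste0("fold", f))
    model <- train_penet(model, list(vols = std$train$vols,
                                     scalars = std$train$scalars,
                                     y = y_tr), fold_cfg)
    probs <- predict(model, list(vols = std$apply$vols,
                                 scalars = std$apply$scalars))
    p_fd <- probs[, "FD"]
    oof_prob[test_idx] <- p_fd
    pred <- factor(ifelse(p_fd >= 0.5, "FD", "MD"), levels = c("MD", "FD"))
    truth <- labels[test_idx]
    fold_results[[f]] <- list(
      fold = f, subject_ids = cohort$subject_ids[test_idx],
      prob_fd = p_fd, accuracy = mean(pred == truth),
      auc = if (nlevels(droplevels(truth)) == 2L) auc(p_fd, truth) else NA,
      confusion = table(pred = pred, truth = truth))
  }
  acc <- vapply(fold_results, `[[`, numeric(1), "accuracy")
  pooled_pred <- factor(ifelse(oof_prob >= 0.5, "FD", "MD"),
                        levels = c("MD", "FD"))
  structure(list(
    fold_results = fold_results, folds = folds,
    oof = data.frame(subject_id = cohort$subject_ids, label = labels,
                     prob_fd = oof_prob, pred = pooled_pred),
    summary = list(accuracy_mean = mean(acc), accuracy_sd = sd(acc),
                   fold_accuracy = acc,
                   pooled_accuracy = mean(pooled_pred == labels),
                   pooled_auc = auc(oof_prob, labels)),
    spec = spec, config = config), class = "penet_cv")
}

# Expand the training bundle with augmented volume copies (labels and
# scalars are duplicated unchanged; subject ids are tracked for the guard).
augment_training_volumes <- function(tr, y, config, seed) {
  n <- dim(tr$vols)[5L]
  copies <- config$augment_copies
  withr::with_seed(seed, {
    shp <- dim(tr$vols)[1:3]
    total <- n * (1L + copies)
    vols <- array(0, c(shp, 1L, total))
    vols[, , , , seq_len(n)] <- tr$vols
    pos <- n
    src <- seq_len(n)
    for (cc in seq_len(copies))
      for (i in seq_len(n)) {
        pos <- pos + 1L
        vols[, , , 1L, pos] <- augment_volume(tr$vols[, , , 1L, i],
                                              config$augment)
        src <- c(src, i)
      }
    list(data = list(vols = vols,
                     scalars = lapply(tr$scalars, function(v) v[src]),
                     subject_ids = tr$subject_ids[src]),
         y = y[src], source_ids = tr$subject_ids[src])
  })
}

#' @export
print.penet_cv <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "PENet %d-fold CV (%s): accuracy %.3f +/- %.3f (pooled %.3f), AUC %.3f\n",
    length(x$fold_results),
    paste(x$spec$enabled_modalities, collapse = "+"),
    s$accuracy_mean, s$accuracy_sd, s$pooled_accuracy, s$pooled_auc))
  invisible(x)
}
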