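#' Area under the ROC curve
#'
#' Computed in the Mann--Whitney form: the fraction of (positive, negative)
#' score pairs ordered correctly, ties counted one half. Identical (up to
#' floating point) to the trapezoidal integral of the ROC curve from
#' [roc_points()].
#'
#' @param scores numeric prediction scores (higher = more positive).
#' @param labels two-class labels; the positive class is `positive`, or by
#'   default the second factor level / the value 1.
#' @param positive optional positive-class value.
#' @return AUC in \[0, 1\].
#' @export
#' @examples
#' auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))  # 0.75
auc <- function(scores, labels, positive = NULL) {
  pos <- positive_mask(labels, positive)
  m <- sum(pos); n <- sum(!pos)
  if (m == 0L || n == 0L)
    abort("AUC undefined: both classes must be present",
          "atnprog_undefined_auc_error")
  r <- rank(scores)
  (sum(r[pos]) - m * (m + 1) / 2) / (m * n)
}

positive_mask <- function(labels, positive = NULL) {
  if (!is.null(positive)) return(labels == positive)
  if (is.factor(labels)) return(labels == levels(labels)[nlevels(labels)])
  u <- sort(unique(labels))
  if (length(u) > 2L) abort("labels must be two-class",
                            "atnprog_undefined_auc_error")
  labels == u[length(u)]
}

#' ROC curve points
#'
#' Thresholds sweep the distinct score values from high to low; tied scores
#' move together, so the curve starts at (0, 0), ends at (1, 1) and is
#' monotone non-decreasing in both coordinates.
#'
#' @inheritParams auc
#' @return data frame with `threshold`, `fpr`, `tpr` (first row is the
#'   (0, 0) corner with threshold `Inf`).
#' @export
roc_points <- function(scores, labels, positive = NULL) {
  pos <- positive_mask(labels, positive)
  m <- sum(pos); n <- sum(!pos)
  if (m == 0L || n == 0L)
    abort("ROC undefined: both classes must be present",
          "atnprog_undefined_auc_error")
  ths <- sort(unique(scores), decreasing = TRUE)
  tp <- cumsum(vapply(ths, function(t) sum(pos & scores == t), numeric(1)))
  fp <- cumsum(vapply(ths, function(t) sum(!pos & scores == t), numeric(1)))
  data.frame(threshold = c(Inf, ths),
             fpr = c(0, fp / n), tpr = c(0, tp / m))
}

#' DeLong test for (differences in) AUC
#'
#' Nonparametric AUC inference via placement values (structural
#' components). With one score vector the single-model AUC is compared
#' against the chance value 0.5 using its estimated variance; with two
#' paired score vectors on the same subjects the correlated AUC difference
#' is tested.
#'
#' @param scores_a scores of the first model.
#' @param scores_b optional scores of a second model, paired by subject.
#' @param labels two-class labels shared by both score vectors.
#' @param positive optional positive-class value.
#' @return list with `auc_a`, `auc_b` (or `NULL`), `auc_diff`, `se`, `z`,
#'   `p_value` (two-sided).
#' @export
delong_test <- function(scores_a, scores_b = NULL, labels, positive = NULL) {
  pos <- positive_mask(labels, positive)
  m <- sum(pos); n <- sum(!pos)
  if (m == 0L || n == 0L)
    abort("DeLong test needs both classes", "atnprog_undefined_auc_error")
  if (length(scores_a) != length(labels) ||
      (!is.null(scores_b) && length(scores_b) != length(labels)))
    abort("scores must be paired with labels on identical subjects",
          "atnprog_pairing_error")
  placements <- function(s) {
    x <- s[pos]; y <- s[!pos]
    r_all <- rank(c(x, y))
    v10 <- (r_all[seq_len(m)] - rank(x)) / n        # per-positive placements
    v01 <- 1 - (r_all[m + seq_len(n)] - rank(y)) / m
    list(v10 = v10, v01 = v01, auc = mean(v10))
  }
  pa <- placements(scores_a)
  if (is.null(scores_b)) {
    v <- var(pa$v10) / m + var(pa$v01) / n
    se <- sqrt(v)
    diff <- pa$auc - 0.5
    z <- if (se == 0) 0 else diff / se
    p <- if (se == 0) as.numeric(diff == 0) else 2 * pnorm(-abs(z))
    return(list(auc_a = pa$auc, auc_b = NULL, auc_diff = diff, se = se,
                z = z, p_value = p))
  }
  pb <- placements(scores_b)
  s10 <- cov(cbind(pa$v10, pb$v10))
  s01 <- cov(cbind(pa$v01, pb$v01))
  v <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  se <- sqrt(max(v, 0))
  diff <- pa$auc - pb$auc
  z <- if (se == 0) 0 else diff / se
  p <- if (se == 0) as.numeric(diff == 0) else 2 * pnorm(-abs(z))
  list(auc_a = pa$auc, auc_b = pb$auc, auc_diff = diff, se = se, z = z,
       p_value = p)
}

# Canonical biomarker-combination labels -> enabled modalities.
combination_modalities <- function(label) {
  switch(label,
         n = c("mri", "fdg"),
         an = c("mri", "fdg", "abeta"),
         tn = c("mri", "fdg", "ptau"),
         atn = c("mri", "fdg", "abeta", "ptau"),
         n_icv = c("mri", "fdg", "icv"),
         mri_only = "mri",
         n_noise = c("mri", "fdg", "noise"),
         abort(sprintf("unknown biomarker combination '%s'", label),
               "atnprog_config_error"))
}

#' Run the AT(N) biomarker-combination ablation
#'
#' Trains and cross-validates one PENet per biomarker combination with
#' identical folds and seeds across combinations (paired design), so
#' performance differences are attributable to the inputs alone. Supported
#' combination labels: `n` (MRI + FDG), `an`, `tn`, `atn`, `n_icv`,
#' `mri_only`, and `n_noise` (N plus a pure-noise scalar probe, drawn
#' once under a seed derived from the config seed).
#'
#' @param cohort an `atn_cohort` with volumes.
#' @param combinations character vector of combination labels.
#' @param spec a [penet_spec()]; its `enabled_modalities` are overridden per
#'   combination.
#' @param config a [train_config()].
#' @param labels per-subject labels (default: the cohort's `true_class`).
#' @return object of class `atn_ablation`: named list of per-combination
#'   results (fold accuracy mean/sd, pooled accuracy, pooled AUC, ROC
#'   points, out-of-fold probabilities) plus the shared `folds`.
#' @export
run_ablation <- function(cohort, combinations = c("n", "tn", "atn"),
                         spec = desk_penet_spec(),
                         config = desk_train_config(),
                         labels = cohort$true_class) {
  labels <- as.factor(labels)
  folds <- stratified_folds(labels, config$folds, config$seed)
  noise <- NULL
  if ("n_noise" %in% combinations)
    noise <- withr::with_seed(derive_seed(config$seed, "noise-scalar"),
                              rnorm(length(labels)))
  results <- list()
  for (comb in combinations) {
    sp <- spec
    sp$enabled_modalities <- combination_modalities(comb)
    validate_penet_spec(sp)
    cv <- train_cv(cohort, sp, config, labels = labels, folds = folds,
                   extra_scalars = if (comb == "n_noise")
                     list(noise = noise) else NULL)
    results[[comb]] <- list(
      combination = comb,
      accuracy_mean = cv$summary$accuracy_mean,
      accuracy_sd = cv$summary$accuracy_sd,
      pooled_accuracy = cv$summary$pooled_accuracy,
      auc = cv$summary$pooled_auc,
      roc = roc_points(cv$oof$prob_fd, labels),
      oof = cv$oof)
  }
  structure(list(results = results, folds = folds, config = config),
            class = "atn_ablation")
}

#' @export
print.atn_ablation <- function(x, ...) {
  for (r in x$results)
    cat(sprintf("%-8s accuracy %.3f +/- %.3f (pooled %.3f), AUC %.3f\n",
                r$combination, r$accuracy_mean, r$accuracy_sd,
                r$pooled_accuracy, r$auc))
  invisible(x)
}

#' Cross-validated scalar baseline classifiers
#'
#' Logistic regression or RBF-kernel SVM on tabular features under the same
#' stratified folds as the deep model. Constant feature columns are dropped
#' with a warning. For an imaging-input SVM comparison see
#' [svm_imaging_features()].
#'
#' @param features numeric matrix or data frame (rows = subjects).
#' @param labels two-class labels.
#' @param model `"logistic"` or `"svm_rbf"`.
#' @param folds fold index sets or an integer fold count.
#' @param seed seed used when folds are computed here.
#' @return list with `accuracy_mean`, `accuracy_sd`, `fold_accuracy`,
#'   `oof_prob` (logistic only), `folds`.
#' @export
scalar_baseline <- function(features, labels,
                            model = c("logistic", "svm_rbf"), folds = 5,
                            seed = 1L) {
  model <- match.arg(model)
  X <- as.matrix(features)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  labels <- as.factor(labels)
  if (is.numeric(folds) && length(folds) == 1L)
    folds <- stratified_folds(labels, folds, seed)
  validate_folds(folds, nrow(X))
  oof <- rep(NA_real_, nrow(X))
  accs <- numeric(length(folds))
  for (f in seq_along(folds)) {
    te <- folds[[f]]
    tr <- setdiff(seq_len(nrow(X)), te)
    sds <- apply(X[tr, , drop = FALSE], 2L, sd)
    keep <- sds > 0
    if (!all(keep))
      warning(sprintf("dropping constant feature(s): %s",
                      paste(colnames(X)[!keep], collapse = ", ")))
    Xtr <- scale(X[tr, keep, drop = FALSE])
    Xte <- scale(X[te, keep, drop = FALSE],
                 center = attr(Xtr, "scaled:center"),
                 scale = attr(Xtr, "scaled:scale"))
    if (model == "logistic") {
      df_tr <- data.frame(Xtr, y = labels[tr])
      fit <- suppressWarnings(glm(y ~ ., data = df_tr, family = binomial()))
      p <- predict(fit, newdata = data.frame(Xte), type = "response")
      oof[te] <- p
      pred <- levels(labels)[1L + (p >= 0.5)]
    } else {
      fit <- e1071::svm(Xtr, labels[tr], kernel = "radial", scale = FALSE)
      pred <- as.character(predict(fit, Xte))
    }
    accs[f] <- mean(pred == labels[te])
  }
  list(accuracy_mean = mean(accs), accuracy_sd = sd(accs),
       fold_accuracy = accs, oof_prob = oof, folds = folds, model = model)
}

#' Imaging feature reduction for the SVM baseline
#'
#' Downsamples each standardised phantom volume to a small grid (default
#' 8^3), flattens it and appends the FDG composite, giving the SVM a
#' tabular representation of the N biomarkers.
#'
#' @param cohort an `atn_cohort` with volumes.
#' @param grid downsampled grid edge length.
#' @return numeric feature matrix.
#' @export
svm_imaging_features <- function(cohort, grid = 8L) {
  stopifnot(!is.null(cohort$volumes))
  feats <- t(vapply(cohort$volumes, function(v) {
    z <- resample_volume(v, rep(grid, 3L))
    as.numeric((z - mean(z)) / sd(z))
  }, numeric(grid^3)))
  cbind(feats, fdg = cohort$biomarkers$fdg)
}

#' Biomarker redundancy analysis between reduced models
#'
#' Tests whether phenotypes predicted from A(N) inputs differ in the
#' held-out tau biomarker, and whether phenotypes predicted from T(N)
#' inputs differ in the held-out amyloid biomarker. Each direction applies
#' [group_difference()] to the out-of-fold predicted labels.
#'
#' @param cohort an `atn_cohort`.
#' @param predictions_an factor of predicted labels from the A(N) model.
#' @param predictions_tn factor of predicted labels from the T(N) model.
#' @param method test passed to [group_difference()].
#' @return list with `ptau_by_an_groups` and `abeta_by_tn_groups`.
#' @export
redundancy_analysis <- function(cohort, predictions_an, predictions_tn,
                                method = "ranksum") {
  list(ptau_by_an_groups = group_difference(cohort$biomarkers$ptau,
                                            predictions_an, method),
       abeta_by_tn_groups = group_difference(cohort$biomarkers$abeta,
                                             predictions_tn, method))
}

#' Compare ablation combinations against a reference by DeLong test
#'
#' Pairwise DeLong tests of each combination's pooled out-of-fold scores
#' against a reference combination (paired by subject). Multiple-comparison
#' correction is off by default; any [stats::p.adjust()] method (e.g.
#' `"holm"`) can be requested.
#'
#' @param ablation an `atn_ablation`.
#' @param reference combination label to compare against (default `"n"`).
#' @param adjust p-value adjustment method (default `"none"`).
#' @return data frame with combination, AUCs, AUC difference, z and
#'   (adjusted) p-value.
#' @export
compare_combinations <- function(ablation, reference = "n",
                                 adjust = "none") {
  stopifnot(inherits(ablation, "atn_ablation"))
  if (!reference %in% names(ablation$results))
    abort(sprintf("reference combination '%s' not in the ablation",
                  reference), "atnprog_config_error")
  ref <- ablation$results[[reference]]
  others <- setdiff(names(ablation$results), reference)
  rows <- lapply(others, function(nm) {
    r <- ablation$results[[nm]]
    dl <- delong_test(r$oof$prob_fd, ref$oof$prob_fd, ref$oof$label)
    data.frame(combination = nm, reference = reference,
               auc = dl$auc_a, auc_ref = dl$auc_b,
               auc_diff = dl$auc_diff, z = dl$z, p_value = dl$p_value)
  })
  out <- do.call(rbind, rows)
  out$p_value <- p.adjust(out$p_value, method = adjust)
  out
}
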