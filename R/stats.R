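#' Pipeline-honest permutation test for post-clustering group differences
#'
#' Tests whether two clusters found in longitudinal trajectories are more
#' separated than expected under a single homogeneous population, while
#' accounting for the fact that the labels came from clustering the same
#' data. The test statistic is the DTW distance between the two cluster mean
#' trajectories. The null distribution is built by re-running the complete
#' cluster-then-compute pipeline on label-free null datasets: each null
#' replicate adds column-wise independently permuted residuals (scores minus
#' the grand mean trajectory) back onto the grand mean, re-clusters at
#' `k = 2` with the same linkage, and recomputes the statistic. The p-value
#' is `(1 + #{null >= observed}) / (1 + n_perm)`.
#'
#' This is a methodological stand-in for selective-inference procedures for
#' post-clustering testing: it preserves type-I control when residuals are
#' independent across visits (true of the bundled generator; see the methods
#' vignette for the assumption and its limits).
#'
#' @param trajectories subjects-by-visits score matrix or cohort
#'   `trajectories` list.
#' @param labels two-level cluster labels (from the clustering pipeline).
#' @param n_perm number of null replicates (at least 100).
#' @param seed integer seed; the result is deterministic given it.
#' @param linkage linkage used when re-clustering null replicates.
#' @return list with `statistic`, `p_value`, `n_perm`, `null_stats`.
#' @export
permutation_cluster_test <- function(trajectories, labels, n_perm = 999,
                                     seed = 1L, linkage = "ward2") {
  x <- if (is.list(trajectories) && !is.data.frame(trajectories))
    as.matrix(trajectories$scores) else as.matrix(trajectories)
  labels <- as.factor(labels)
  if (nlevels(labels) != 2L)
    abort("permutation test requires exactly two cluster labels",
          "atnprog_config_error")
  if (min(table(labels)) < 2L)
    abort("each cluster must have at least 2 subjects",
          "atnprog_degenerate_cluster_error")
  if (n_perm < 100L)
    abort("n_perm must be at least 100", "atnprog_config_error")

  stat_for <- function(scores, lab) {
    m1 <- colMeans(scores[lab == levels(lab)[1L], , drop = FALSE])
    m2 <- colMeans(scores[lab == levels(lab)[2L], , drop = FALSE])
    dtw_distance(m1, m2)
  }
  obs <- stat_for(x, labels)
  mu <- colMeans(x)
  res <- sweep(x, 2L, mu)
  n <- nrow(x)
  null_stats <- withr::with_seed(seed, vapply(seq_len(n_perm), function(b) {
    rb <- apply(res, 2L, function(col) col[sample.int(n)])
    xb <- sweep(rb, 2L, mu, `+`)
    clb <- hierarchical_cluster(cpp_pairwise_dtw(xb), linkage, 2L)
    stat_for(xb, factor(clb$labels))
  }, numeric(1)))
  list(statistic = obs,
       p_value = (1 + sum(null_stats >= obs)) / (1 + n_perm),
       n_perm = as.integer(n_perm), null_stats = null_stats)
}

#' Two-way mixed-design (repeated measures) ANOVA
#'
#' Classical two-way repeated-measures ANOVA with a between-subject factor
#' (phenotype group) and a within-subject factor (visit), subjects as the
#' within-error stratum, on a complete balanced panel. Returns the main
#' effect of time and the time-by-group interaction in the
#' `F(t - 1, (n - g)(t - 1))` reporting format. No sphericity correction is
#' applied by default; `gg_correction = TRUE` applies the
#' Greenhouse--Geisser epsilon to degrees of freedom and p-values.
#'
#' @param scores subjects-by-time score matrix.
#' @param group between-subject factor, one level per subject.
#' @param time_labels optional labels for the time points.
#' @param gg_correction apply Greenhouse--Geisser correction.
#' @return object of class `rm_anova`: `F_time`, `df_time`, `p_time`,
#'   `F_interaction`, `df_interaction`, `p_interaction` (plus `epsilon` if
#'   corrected).
#' @export
rm_anova <- function(scores, group, time_labels = NULL,
                     gg_correction = FALSE) {
  scores <- as.matrix(scores)
  group <- droplevels(as.factor(group))
  n <- nrow(scores); t <- ncol(scores); g <- nlevels(group)
  if (length(group) != n)
    abort("one group label per subject required", "atnprog_balance_error")
  if (anyNA(scores))
    abort("panel must be complete (no missing cells)", "atnprog_balance_error")
  time_labels <- time_labels %||% colnames(scores) %||% paste0("t", seq_len(t))

  long <- data.frame(
    score = as.vector(scores),
    subject = factor(rep(seq_len(n), times = t)),
    group = rep(group, times = t),
    time = factor(rep(time_labels, each = n), levels = time_labels))
  fit <- aov(score ~ group * time + Error(subject), data = long)
  tab <- summary(fit)[["Error: Within"]][[1L]]
  rn <- trimws(rownames(tab))
  row_time <- which(rn == "time")
  row_int <- which(rn == "group:time")
  row_res <- which(rn == "Residuals")
  ss <- tab[["Sum Sq"]]; df <- tab[["Df"]]
  # guard against floating-point dust when the panel is (near-)constant
  eps <- 1e-12 * max(sum(ss), 1)
  ss[ss < eps] <- 0
  ms_res <- ss[row_res] / df[row_res]
  f_of <- function(r) {
    ms <- ss[r] / df[r]
    if (ms_res == 0) { if (ss[r] == 0) 0 else Inf } else ms / ms_res
  }
  F_time <- f_of(row_time); F_int <- f_of(row_int)
  df_time <- c(df[row_time], df[row_res])
  df_int <- c(df[row_int], df[row_res])
  eps <- 1
  if (gg_correction) {
    # Greenhouse-Geisser epsilon from the pooled within-group covariance
    centred <- scores - rowsum(scores, group)[group, ] / as.vector(table(group))[group]
    S <- crossprod(centred) / (n - g)
    dbar <- mean(diag(S)); mbar <- mean(S)
    num <- (t * (dbar - mbar))^2
    den <- (t - 1) * (sum(S^2) - 2 * t * sum(rowMeans(S)^2) + t^2 * mbar^2)
    eps <- max(1 / (t - 1), min(1, num / den))
  }
  p_time <- stats::pf(F_time, df_time[1] * eps, df_time[2] * eps,
                      lower.tail = FALSE)
  p_int <- stats::pf(F_int, df_int[1] * eps, df_int[2] * eps,
                     lower.tail = FALSE)
  if (F_time == 0) p_time <- 1
  if (F_int == 0) p_int <- 1
  structure(list(F_time = F_time, df_time = df_time, p_time = p_time,
                 F_interaction = F_int, df_interaction = df_int,
                 p_interaction = p_int,
                 epsilon = if (gg_correction) eps else NULL),
            class = "rm_anova")
}

#' @export
print.rm_anova <- function(x, ...) {
  cat(sprintf("time:        F(%d, %d) = %.3f, p = %.3g\n",
              x$df_time[1], x$df_time[2], x$F_time, x$p_time))
  cat(sprintf("interaction: F(%d, %d) = %.3f, p = %.3g\n",
              x$df_interaction[1], x$df_interaction[2], x$F_interaction,
              x$p_interaction))
  invisible(x)
}

#' Two-group difference test
#'
#' Welch two-sided t test or Wilcoxon rank-sum test for comparing a
#' continuous measure across two groups (demographics, biomarker redundancy
#' analyses, ...).
#'
#' @param values numeric vector.
#' @param labels two-level grouping factor.
#' @param method `"t"` (Welch) or `"ranksum"`.
#' @return list with `statistic`, `p_value`, `method`, group `means`.
#' @export
group_difference <- function(values, labels, method = c("t", "ranksum")) {
  method <- match.arg(method)
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) != 2L)
    abort("exactly two groups required", "atnprog_degenerate_group_error")
  sp <- split(values, labels)
  if (any(lengths(sp) < 2L))
    abort("each group needs at least 2 observations",
          "atnprog_degenerate_group_error")
  if (method == "t") {
    if (var(sp[[1]]) == 0 && var(sp[[2]]) == 0)
      abort("zero variance in both groups", "atnprog_degenerate_group_error")
    ht <- t.test(sp[[1]], sp[[2]], var.equal = FALSE)
  } else {
    ht <- suppressWarnings(wilcox.test(sp[[1]], sp[[2]]))
  }
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       method = method,
       means = vapply(sp, mean, numeric(1)))
}

#' Tau positivity from CSF p-tau
#'
#' Strict threshold rule: a subject is T+ iff CSF p-tau exceeds the cutoff
#' (default 21.8 pg/mL). Missing values propagate as `NA` with a warning.
#'
#' @param ptau numeric CSF p-tau values in pg/mL.
#' @param cutoff positivity cutoff in pg/mL.
#' @return logical vector (`NA` where `ptau` is missing).
#' @export
#' @examples
#' tau_positive(c(10, 22, 21.8, 30))
tau_positive <- function(ptau, cutoff = 21.8) {
  if (anyNA(ptau)) warning("missing p-tau values flagged as NA")
  ptau > cutoff
}

#' Pearson chi-square test on a contingency table
#'
#' Pearson chi-square without continuity correction, df = (r-1)(c-1),
#' upper-tail p from the chi-square distribution. Zero row or column margins
#' and non-positive expected counts are rejected.
#'
#' @param table r-by-c matrix (or table) of non-negative counts.
#' @return object of class `contingency_result`: `table`, `chi2`, `df`, `p`,
#'   `expected`.
#' @export
#' @examples
#' chi_square(matrix(c(10, 10, 10, 10), 2))
chi_square <- function(table) {
  tab <- as.matrix(table)
  if (any(tab < 0) || any(tab != round(tab)))
    abort("counts must be non-negative integers", "atnprog_config_error")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    abort("zero row/column margin", "atnprog_margin_error")
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected <= 0))
    abort("all expected counts must be positive", "atnprog_margin_error")
  ht <- suppressWarnings(chisq.test(tab, correct = FALSE))
  structure(list(table = tab, chi2 = unname(ht$statistic),
                 df = unname(ht$parameter), p = ht$p.value,
                 expected = expected),
            class = "contingency_result")
}

#' @export
print.contingency_result <- function(x, ...) {
  print(x$table)
  cat(sprintf("chi2 = %.3f, df = %d, p = %.3g\n", x$chi2, x$df, x$p))
  invisible(x)
}
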