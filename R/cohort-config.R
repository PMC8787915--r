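#' Configuration for the synthetic cohort generator
#'
#' Defines the statistical structure of a simulated Alzheimer's-continuum
#' cohort: two latent decline classes (moderate decliners, MD, and fast
#' decliners, FD), their cognitive-trajectory parameters on an MMSE-like
#' 0--30 scale, class-dependent atrophy of phantom brain volumes, and
#' class-conditional baseline biomarker distributions for CSF amyloid-beta,
#' CSF p-tau, an FDG-PET composite, amyloid-PET SUVR and intracranial volume.
#'
#' Trajectories follow \eqn{score(t) = baseline + slope \cdot t +
#' nonlinearity \cdot t^2 + \epsilon} with \eqn{t} in years and independent
#' Gaussian visit noise. When `synergy_coefficient` is non-zero the class
#' labels are instead drawn from a logistic model on independent standard
#' latents \eqn{z_A, z_T, z_N} with main effects plus an \eqn{z_A z_T}
#' product term, so that the joint AT(N) information exceeds any marginal
#' subset; observed biomarkers become readouts of those latents and
#' trajectories follow the final class (see the methods vignette).
#'
#' @param n_subjects number of subjects (at least 4).
#' @param class_proportions named probabilities for MD and FD; must sum to 1.
#' @param visit_months strictly increasing non-negative visit months; the
#'   default `c(0, 6, 12, 24)` gives four visits across 24 months.
#' @param trajectory_params per-class list with `baseline_mean`,
#'   `baseline_sd`, `slope_mean`, `slope_sd` (score units per year),
#'   `nonlinearity` (score units per year squared) and `noise_sd`.
#' @param volume_shape 3 positive integers (each at least 8): phantom voxel
#'   grid.
#' @param voxel_size_mm isotropic voxel size recorded in NIfTI headers.
#' @param atrophy_params per-class hippocampal and cortical intensity scale
#'   factors in (0, 1].
#' @param biomarker_params per-class mean/sd for `abeta` (pg/mL), `ptau`
#'   (pg/mL), `fdg` (unitless composite), `suvr` (unitless) and `icv`
#'   (mm^3).
#' @param synergy_coefficient weight of the amyloid-by-tau interaction on the
#'   class log-odds; 0 disables the logistic label-refinement mode.
#' @param label_model coefficients of the label-refinement logistic model
#'   (intercept and standardized A, T, N main effects).
#' @param missing_fdg_prob,missing_suvr_prob per-subject probability of a
#'   missing FDG composite / SUVR value.
#' @param generate_volumes logical; skip phantom volume synthesis for
#'   trajectory-only analyses.
#' @param secondary_scales logical; also emit ADAS-Cog13-, CDR-SB- and
#'   FAQ-like secondary panels (higher = worse) derived from the same latent
#'   decline.
#' @param seed integer seed; the whole cohort is a deterministic function of
#'   the configuration including this seed.
#' @return an object of class `cohort_config`.
#' @seealso [generate_cohort()], [synergy_cohort_config()]
#' @export
cohort_config <- function(n_subjects = 300,
                          class_proportions = c(MD = 0.6, FD = 0.4),
                          visit_months = c(0, 6, 12, 24),
                          trajectory_params = list(
                            MD = list(baseline_mean = 27, baseline_sd = 1.2,
                                      slope_mean = -1.2, slope_sd = 0.4,
                                      nonlinearity = -0.05, noise_sd = 1.0),
                            FD = list(baseline_mean = 25.5, baseline_sd = 1.2,
                                      slope_mean = -4.5, slope_sd = 0.8,
                                      nonlinearity = -0.35, noise_sd = 1.0)),
                          volume_shape = c(32, 32, 32),
                          voxel_size_mm = 5,
                          atrophy_params = list(
                            MD = list(hippocampal = 0.85, cortical = 0.90),
                            FD = list(hippocampal = 0.65, cortical = 0.80)),
                          biomarker_params = list(
                            MD = list(abeta = c(820, 180), ptau = c(24, 7),
                                      fdg = c(1.25, 0.11), suvr = c(1.25, 0.12),
                                      icv = c(1.5e6, 1.5e5)),
                            FD = list(abeta = c(640, 150), ptau = c(33, 9),
                                      fdg = c(1.05, 0.11), suvr = c(1.40, 0.12),
                                      icv = c(1.5e6, 1.5e5))),
                          synergy_coefficient = 0,
                          label_model = c(intercept = -0.3, a = 0.5,
                                          t = 1.1, n = 1.0),
                          missing_fdg_prob = 0,
                          missing_suvr_prob = 0,
                          generate_volumes = TRUE,
                          secondary_scales = TRUE,
                          seed = 1L) {
  cfg <- structure(
    list(n_subjects = as.integer(n_subjects),
         class_proportions = class_proportions,
         n_timepoints = length(visit_months),
         visit_months = visit_months,
         trajectory_params = trajectory_params,
         volume_shape = as.integer(volume_shape),
         voxel_size_mm = voxel_size_mm,
         atrophy_params = atrophy_params,
         biomarker_params = biomarker_params,
         synergy_coefficient = synergy_coefficient,
         label_model = label_model,
         missing_fdg_prob = missing_fdg_prob,
         missing_suvr_prob = missing_suvr_prob,
         generate_volumes = isTRUE(generate_volumes),
         secondary_scales = isTRUE(secondary_scales),
         seed = as.integer(seed)),
    class = "cohort_config")
  validate_cohort_config(cfg)
  cfg
}

#' Preset configuration with amyloid-by-tau synergy
#'
#' Convenience wrapper around [cohort_config()] enabling the logistic
#' label-refinement mode, used throughout the package as the default
#' "synergy cohort" for the biomarker ablation experiments: tau and
#' neurodegeneration carry strong main effects, amyloid a weaker main effect
#' plus the product term, so Bayes-optimal accuracy is ordered
#' AT(N) > T(N) > N.
#'
#' @param n_subjects number of subjects.
#' @param synergy_coefficient interaction weight (default 2).
#' @param seed integer seed.
#' @param ... further arguments passed to [cohort_config()].
#' @return a `cohort_config`.
#' @export
synergy_cohort_config <- function(n_subjects = 200, synergy_coefficient = 2,
                                  seed = 1L, ...) {
  cohort_config(n_subjects = n_subjects,
                synergy_coefficient = synergy_coefficient,
                seed = seed, ...)
}

validate_cohort_config <- function(cfg) {
  num_ok <- function(x) all(vapply(x, function(v) all(is.finite(unlist(v))),
                                   logical(1)))
  if (!num_ok(cfg$trajectory_params) || !num_ok(cfg$biomarker_params) ||
      !num_ok(cfg$atrophy_params) || !all(is.finite(cfg$label_model)) ||
      !is.finite(cfg$synergy_coefficient))
    abort("non-finite generator parameter", "atnprog_config_error")
  if (cfg$n_subjects < 4L)
    abort("n_subjects must be at least 2 per class", "atnprog_cohort_size_error")
  if (abs(sum(cfg$class_proportions) - 1) > 1e-12)
    abort("class proportions must sum to 1", "atnprog_config_error")
  if (any(cfg$class_proportions < 0))
    abort("class proportions must be non-negative", "atnprog_config_error")
  if (length(cfg$volume_shape) != 3L || any(cfg$volume_shape < 8L))
    abort("volume_shape must be 3 integers, each >= 8", "atnprog_config_error")
  if (any(diff(cfg$visit_months) <= 0) || any(cfg$visit_months < 0))
    abort("visit_months must be non-negative and strictly increasing",
          "atnprog_config_error")
  sds <- c(vapply(cfg$trajectory_params,
                  function(p) c(p$baseline_sd, p$slope_sd, p$noise_sd),
                  numeric(3)),
           vapply(cfg$biomarker_params,
                  function(p) vapply(p, `[`, numeric(1), 2L), numeric(5)))
  if (any(sds < 0)) abort("all sds must be >= 0", "atnprog_config_error")
  scales <- unlist(cfg$atrophy_params)
  if (any(scales <= 0) || any(scales > 1))
    abort("atrophy scale factors must lie in (0, 1]", "atnprog_config_error")
  invisible(cfg)
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  subjects: %d (MD %.2f / FD %.2f)\n", x$n_subjects,
              x$class_proportions[["MD"]], x$class_proportions[["FD"]]))
  cat(sprintf("  visits (months): %s\n", paste(x$visit_months, collapse = ", ")))
  cat(sprintf("  volume shape: %s (%.1f mm voxels)%s\n",
              paste(x$volume_shape, collapse = "x"), x$voxel_size_mm,
              if (x$generate_volumes) "" else " [volumes disabled]"))
  cat(sprintf("  synergy coefficient: %g\n", x$synergy_coefficient))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}
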