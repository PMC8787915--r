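#' Generate a synthetic Alzheimer's-continuum cohort
#'
#' Draws a full per-subject bundle — longitudinal cognitive trajectories,
#' phantom 3D volumes, baseline scalar biomarkers, regional volumes and
#' demographics — with the statistical structure the downstream analysis
#' assumes: two decline classes with class-dependent trajectory slopes and
#' atrophy, and (optionally) class labels governed by a logistic AT(N) model
#' with an amyloid-by-tau synergy term.
#'
#' The phantom volumes are piecewise-constant "brains": a cortex-like
#' ellipsoidal shell and two hippocampus-like ellipsoids on a zero-mean noise
#' background, with region intensities scaled by the subject's atrophy
#' factors. They carry class-informative spatial signal for the volume
#' encoder without pretending anatomical realism.
#'
#' The cohort is a deterministic function of the configuration (including its
#' seed): two calls with the same config are identical.
#'
#' @param config a [cohort_config()].
#' @return an object of class `atn_cohort`: a list with `subject_ids`,
#'   `true_class` (factor MD/FD), `trajectories` (list with `scores` matrix
#'   and `visit_months`), `volumes` (list of 3D arrays or `NULL`),
#'   `voxel_size_mm`, `biomarkers`, `regional_volumes`, `demographics` data
#'   frames, `secondary` score panels, `latents` (synergy mode only) and the
#'   `config`.
#' @export
#' @examples
#' coh <- generate_cohort(cohort_config(n_subjects = 20,
#'                                      generate_volumes = FALSE))
#' table(coh$true_class)
generate_cohort <- function(config) {
  validate_cohort_config(config)
  withr::with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(config) {
  n <- config$n_subjects
  ids <- sprintf("S%04d", seq_len(n))
  t_years <- config$visit_months / 12

  if (config$synergy_coefficient != 0) {
    lat <- data.frame(z_a = rnorm(n), z_t = rnorm(n), z_n = rnorm(n))
    lm_ <- config$label_model
    eta <- lm_[["intercept"]] + lm_[["a"]] * lat$z_a + lm_[["t"]] * lat$z_t +
      lm_[["n"]] * lat$z_n + config$synergy_coefficient * lat$z_a * lat$z_t
    cls <- factor(ifelse(runif(n) < plogis(eta), "FD", "MD"),
                  levels = c("MD", "FD"))
    bm <- biomarkers_from_latents(lat, config)
    atro <- atrophy_from_latents(lat)
  } else {
    lat <- NULL
    n_md <- round(n * config$class_proportions[["MD"]])
    n_md <- min(max(n_md, 2L), n - 2L)  # at least 2 per class
    cls <- factor(sample(rep(c("MD", "FD"), c(n_md, n - n_md))),
                  levels = c("MD", "FD"))
    bm <- biomarkers_by_class(cls, config)
    atro <- atrophy_by_class(cls, config)
  }

  # missingness switches for the FDG-free / PET-free secondary analyses
  if (config$missing_fdg_prob > 0)
    bm$fdg[runif(n) < config$missing_fdg_prob] <- NA_real_
  if (config$missing_suvr_prob > 0)
    bm$suvr[runif(n) < config$missing_suvr_prob] <- NA_real_

  traj <- trajectories_by_class(cls, config)
  sec <- if (config$secondary_scales) secondary_from_mmse(traj$scores) else NULL

  rv <- data.frame(
    subject_id = ids,
    hippocampal_volume = 7400 * atro$hippocampal * exp(rnorm(n, 0, 0.03)),
    cortical_total_volume = 4.5e5 * atro$cortical * exp(rnorm(n, 0, 0.03)))

  vols <- NULL
  if (config$generate_volumes)
    vols <- phantom_volumes(atro, config$volume_shape)

  demo <- data.frame(
    subject_id = ids,
    age = round(rnorm(n, 73.5, 7.5), 1),
    sex = factor(sample(c("m", "f"), n, replace = TRUE, prob = c(0.56, 0.44))),
    education = pmax(6, round(rnorm(n, 16, 2.5))),
    apoe4 = rbinom(n, 1, 0.5),
    # clinical stage mixes differently across phenotypes (MD mostly MCI,
    # FD mostly AD), exercising the relabel-and-retrain harness
    diagnosis = ifelse(cls == "MD",
                       ifelse(runif(n) < 0.63, "MCI", "AD"),
                       ifelse(runif(n) < 0.17, "MCI", "AD")))
  bm$subject_id <- ids
  bm <- bm[, c("subject_id", "abeta", "ptau", "fdg", "suvr", "icv")]

  structure(list(subject_ids = ids,
                 true_class = cls,
                 trajectories = list(scores = traj$scores,
                                     visit_months = config$visit_months),
                 volumes = vols,
                 voxel_size_mm = config$voxel_size_mm,
                 biomarkers = bm,
                 regional_volumes = rv,
                 demographics = demo,
                 secondary = sec,
                 latents = lat,
                 config = config),
            class = "atn_cohort")
}

biomarkers_by_class <- function(cls, config) {
  n <- length(cls)
  draw <- function(name) {
    p <- config$biomarker_params
    m <- ifelse(cls == "MD", p$MD[[name]][1], p$FD[[name]][1])
    s <- ifelse(cls == "MD", p$MD[[name]][2], p$FD[[name]][2])
    pmax(rnorm(n, m, s), 1e-6)  # concentrations and volumes stay positive
  }
  data.frame(abeta = draw("abeta"), ptau = draw("ptau"), fdg = draw("fdg"),
             suvr = draw("suvr"), icv = draw("icv"))
}

# In synergy mode observed markers are readouts of the standard latents:
# abeta and ptau are exact affine transforms (pathological direction: low
# abeta, high ptau), fdg is a noisy readout of z_n (correlation ~0.75).
biomarkers_from_latents <- function(lat, config) {
  n <- nrow(lat)
  p <- config$biomarker_params
  pool <- function(name) {
    m <- (p$MD[[name]][1] + p$FD[[name]][1]) / 2
    s <- (p$MD[[name]][2] + p$FD[[name]][2]) / 2
    c(m, s)
  }
  ab <- pool("abeta"); pt <- pool("ptau"); fd <- pool("fdg")
  sv <- pool("suvr"); ic <- pool("icv")
  rho <- 0.75
  fdg_read <- rho * lat$z_n + sqrt(1 - rho^2) * rnorm(n)
  data.frame(
    abeta = pmax(ab[1] - ab[2] * lat$z_a, 1e-6),
    ptau = pmax(pt[1] + pt[2] * lat$z_t, 1e-6),
    fdg = pmax(fd[1] - fd[2] * fdg_read, 1e-6),
    suvr = pmax(sv[1] + sv[2] * (0.8 * lat$z_a + 0.6 * rnorm(n)), 1e-6),
    icv = pmax(rnorm(n, ic[1], ic[2]), 1e-6))
}

atrophy_by_class <- function(cls, config) {
  n <- length(cls)
  h <- ifelse(cls == "MD", config$atrophy_params$MD$hippocampal,
              config$atrophy_params$FD$hippocampal)
  cv <- ifelse(cls == "MD", config$atrophy_params$MD$cortical,
               config$atrophy_params$FD$cortical)
  list(hippocampal = pmin(pmax(h * exp(rnorm(n, 0, 0.04)), 0.05), 1),
       cortical = pmin(pmax(cv * exp(rnorm(n, 0, 0.04)), 0.05), 1))
}

# Synergy mode: atrophy tracks the neurodegeneration latent so that volumes
# carry class-relevant (but partial) information.
atrophy_from_latents <- function(lat) {
  n <- nrow(lat)
  list(hippocampal = pmin(pmax(0.76 - 0.11 * lat$z_n + rnorm(n, 0, 0.03),
                               0.05), 1),
       cortical = pmin(pmax(0.86 - 0.06 * lat$z_n + rnorm(n, 0, 0.03),
                            0.05), 1))
}

trajectories_by_class <- function(cls, config) {
  n <- length(cls)
  t_years <- config$visit_months / 12
  nt <- length(t_years)
  par <- function(name) {
    p <- config$trajectory_params
    ifelse(cls == "MD", p$MD[[name]], p$FD[[name]])
  }
  baseline <- rnorm(n, par("baseline_mean"), par("baseline_sd"))
  slope <- rnorm(n, par("slope_mean"), par("slope_sd"))
  nonlin <- par("nonlinearity")
  noise_sd <- par("noise_sd")
  scores <- matrix(0, n, nt,
                   dimnames = list(sprintf("S%04d", seq_len(n)),
                                   paste0("m", config$visit_months)))
  for (j in seq_len(nt)) {
    mu <- baseline + slope * t_years[j] + nonlin * t_years[j]^2
    scores[, j] <- mu + rnorm(n, 0, noise_sd)
  }
  list(scores = pmin(pmax(scores, 0), 30))
}

# Secondary panels (higher = worse) are affine readouts of the MMSE-like
# decline with independent visit noise.
secondary_from_mmse <- function(mmse) {
  n <- nrow(mmse); nt <- ncol(mmse)
  mk <- function(scale_, sdev, cap) {
    v <- (30 - mmse) * scale_ + matrix(rnorm(n * nt, 0, sdev), n, nt)
    pmin(pmax(v, 0), cap)
  }
  list(adas13 = mk(2.3, 1.5, 85), cdrsb = mk(0.55, 0.4, 18),
       faq = mk(0.9, 1.0, 30))
}

phantom_masks <- function(shape) {
  d <- shape[1]; h <- shape[2]; w <- shape[3]
  cx <- (d + 1) / 2; cy <- (h + 1) / 2; cz <- (w + 1) / 2
  g <- expand.grid(x = seq_len(d), y = seq_len(h), z = seq_len(w))
  ell <- function(x0, y0, z0, rx, ry, rz)
    ((g$x - x0) / rx)^2 + ((g$y - y0) / ry)^2 + ((g$z - z0) / rz)^2 <= 1
  # radii stay within 0.38 of each extent so the documented augmentation
  # ranges (shifts up to ~10% per axis) keep all content in the field of view
  outer_c <- ell(cx, cy, cz, 0.38 * d, 0.38 * h, 0.36 * w)
  inner_c <- ell(cx, cy, cz, 0.27 * d, 0.27 * h, 0.25 * w)
  cortex <- outer_c & !inner_c
  hip <- ell(cx - 0.12 * d, cy, cz - 0.08 * w, 0.08 * d, 0.08 * h, 0.1 * w) |
    ell(cx + 0.12 * d, cy, cz - 0.08 * w, 0.08 * d, 0.08 * h, 0.1 * w)
  list(cortex = array(cortex, shape), hippocampus = array(hip, shape))
}

phantom_volumes <- function(atro, shape) {
  masks <- phantom_masks(shape)
  n <- length(atro$hippocampal)
  nv <- prod(shape)
  lapply(seq_len(n), function(i) {
    v <- array(rnorm(nv, 0, 0.1), shape)
    v[masks$cortex] <- v[masks$cortex] + 1.0 * atro$cortical[i]
    v[masks$hippocampus] <- v[masks$hippocampus] + 1.6 * atro$hippocampal[i]
    v
  })
}

#' @export
print.atn_cohort <- function(x, ...) {
  cat(sprintf("Synthetic AT(N) cohort: %d subjects (%d MD / %d FD)\n",
              length(x$subject_ids), sum(x$true_class == "MD"),
              sum(x$true_class == "FD")))
  cat(sprintf("  visits (months): %s\n",
              paste(x$trajectories$visit_months, collapse = ", ")))
  cat(sprintf("  volumes: %s\n",
              if (is.null(x$volumes)) "none" else
                paste(dim(x$volumes[[1]]), collapse = "x")))
  cat(sprintf("  synergy mode: %s\n",
              if (x$config$synergy_coefficient != 0) "on" else "off"))
  invisible(x)
}
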