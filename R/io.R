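#' Write a cohort to disk as portable artifacts
#'
#' Emits the tabular pieces as CSV (`trajectories.csv` in long format,
#' `biomarkers.csv`, `regional_volumes.csv`, `demographics.csv`), the
#' phantom volumes as per-subject NIfTI-1 files with an RAS+ diagonal
#' affine and isotropic voxel size, and a JSON manifest. Numeric columns
#' are written with full (17 significant digit) precision so a read/write
#' round trip reproduces the analysis bitwise.
#'
#' @param cohort an `atn_cohort`.
#' @param dir output directory (created if needed).
#' @param write_volumes write NIfTI volumes (can be slow for large
#'   cohorts).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, write_volumes = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  months <- cohort$trajectories$visit_months
  scores <- cohort$trajectories$scores
  long <- data.frame(
    subject_id = rep(cohort$subject_ids, times = length(months)),
    month = rep(months, each = length(cohort$subject_ids)),
    score = as.vector(scores))
  write_csv_full(long, file.path(dir, "trajectories.csv"))
  write_csv_full(cohort$biomarkers, file.path(dir, "biomarkers.csv"))
  write_csv_full(cohort$regional_volumes,
                 file.path(dir, "regional_volumes.csv"))
  write_csv_full(cohort$demographics, file.path(dir, "demographics.csv"))
  vol_files <- NULL
  if (write_volumes && !is.null(cohort$volumes)) {
    vdir <- file.path(dir, "volumes")
    dir.create(vdir, showWarnings = FALSE)
    vs <- cohort$voxel_size_mm
    vol_files <- file.path("volumes", paste0(cohort$subject_ids, ".nii"))
    for (i in seq_along(cohort$volumes)) {
      img <- RNifti::asNifti(cohort$volumes[[i]],
                             pixdim = rep(vs, 3), datatype = "double")
      RNifti::writeNifti(img, file.path(dir, vol_files[i]), compression = 0)
    }
  }
  manifest <- list(
    n_subjects = length(cohort$subject_ids),
    subject_ids = cohort$subject_ids,
    true_class = as.character(cohort$true_class),
    visit_months = months,
    voxel_size_mm = cohort$voxel_size_mm,
    volume_files = vol_files,
    synergy_coefficient = cohort$config$synergy_coefficient,
    seed = cohort$config$seed)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

write_csv_full <- function(df, path) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir directory containing the artifacts.
#' @return an `atn_cohort` (without generator config; `true_class` restored
#'   from the manifest).
#' @export
read_cohort <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  long <- read.csv(file.path(dir, "trajectories.csv"))
  ids <- manifest$subject_ids
  months <- manifest$visit_months
  scores <- matrix(NA_real_, length(ids), length(months),
                   dimnames = list(NULL, paste0("m", months)))
  for (j in seq_along(months)) {
    sel <- long[long$month == months[j], ]
    scores[, j] <- sel$score[match(ids, sel$subject_id)]
  }
  vols <- NULL
  if (!is.null(manifest$volume_files) && length(manifest$volume_files))
    vols <- lapply(manifest$volume_files, function(f) {
      v <- RNifti::readNifti(file.path(dir, f))
      array(as.numeric(v), dim(v))
    })
  structure(list(
    subject_ids = ids,
    true_class = factor(manifest$true_class, levels = c("MD", "FD")),
    trajectories = list(scores = scores, visit_months = months),
    volumes = vols,
    voxel_size_mm = manifest$voxel_size_mm,
    biomarkers = read.csv(file.path(dir, "biomarkers.csv")),
    regional_volumes = read.csv(file.path(dir, "regional_volumes.csv")),
    demographics = read.csv(file.path(dir, "demographics.csv")),
    secondary = NULL, latents = NULL,
    config = list(synergy_coefficient = manifest$synergy_coefficient,
                  seed = manifest$seed)), class = "atn_cohort")
}
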