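#' Amyloid-positivity inclusion filter
#'
#' Applies the study inclusion rule for amyloid positivity: a subject is
#' included if CSF amyloid-beta is below `abeta_cutoff` (pg/mL) or the
#' amyloid-PET uptake ratio exceeds `suvr_cutoff`, both strict inequalities.
#' Subjects qualifying on both measures are counted under the CSF criterion
#' (CSF-first precedence), so the per-criterion counts are disjoint. Subjects
#' with both measures missing are excluded with reason
#' `"no amyloid measure"`.
#'
#' The filter is idempotent and order-independent: re-filtering the included
#' subset returns the same set.
#'
#' @param biomarkers data frame with columns `subject_id`, `abeta`, `suvr`
#'   (`NA` allowed).
#' @param abeta_cutoff CSF amyloid-beta cutoff in pg/mL (default 976.6).
#' @param suvr_cutoff PET uptake-ratio cutoff (default 1.11).
#' @return a list of class `inclusion_filter` with `table` (per-subject
#'   `included` flag and `reason` in csf/pet/amyloid-negative/no amyloid
#'   measure), `included` subject ids, and disjoint `counts`
#'   (`csf`, `pet_only`, `excluded`, `no_measure`).
#' @export
#' @examples
#' bm <- data.frame(subject_id = paste0("S", 1:5),
#'                  abeta = c(900, 1000, 950, 1200, NA),
#'                  suvr = c(NA, 1.2, 1.3, 1.0, 1.5))
#' apply_inclusion_filter(bm)$counts
apply_inclusion_filter <- function(biomarkers, abeta_cutoff = 976.6,
                                   suvr_cutoff = 1.11) {
  stopifnot(is.data.frame(biomarkers),
            all(c("subject_id", "abeta", "suvr") %in% names(biomarkers)))
  ab <- biomarkers$abeta
  sv <- biomarkers$suvr
  no_measure <- is.na(ab) & is.na(sv)
  q_csf <- !is.na(ab) & ab < abeta_cutoff
  q_pet <- !is.na(sv) & sv > suvr_cutoff
  included <- q_csf | q_pet
  reason <- rep("amyloid-negative", nrow(biomarkers))
  reason[q_pet] <- "pet"
  reason[q_csf] <- "csf"  # CSF precedence when both qualify
  reason[no_measure] <- "no amyloid measure"
  tab <- data.frame(subject_id = biomarkers$subject_id,
                    included = included, reason = reason)
  structure(list(table = tab,
                 included = biomarkers$subject_id[included],
                 counts = list(csf = sum(q_csf),
                               pet_only = sum(q_pet & !q_csf),
                               excluded = sum(!included & !no_measure),
                               no_measure = sum(no_measure)),
                 abeta_cutoff = abeta_cutoff, suvr_cutoff = suvr_cutoff),
            class = "inclusion_filter")
}

#' @export
print.inclusion_filter <- function(x, ...) {
  cat(sprintf("Amyloid-positivity filter (CSF < %.1f pg/mL or SUVR > %.2f)\n",
              x$abeta_cutoff, x$suvr_cutoff))
  cat(sprintf("  included: %d (CSF %d, PET-only %d); excluded: %d; no measure: %d\n",
              length(x$included), x$counts$csf, x$counts$pet_only,
              x$counts$excluded, x$counts$no_measure))
  invisible(x)
}

#' Subset a cohort to a set of subjects
#'
#' @param cohort an `atn_cohort`.
#' @param subject_ids ids to keep (order preserved from the cohort).
#' @return the subsetted `atn_cohort`.
#' @export
subset_cohort <- function(cohort, subject_ids) {
  keep <- cohort$subject_ids %in% subject_ids
  out <- cohort
  out$subject_ids <- cohort$subject_ids[keep]
  out$true_class <- cohort$true_class[keep]
  out$trajectories$scores <- cohort$trajectories$scores[keep, , drop = FALSE]
  if (!is.null(cohort$volumes)) out$volumes <- cohort$volumes[keep]
  for (nm in c("biomarkers", "regional_volumes", "demographics"))
    out[[nm]] <- cohort[[nm]][keep, , drop = FALSE]
  if (!is.null(cohort$secondary))
    out$secondary <- lapply(cohort$secondary, function(m) m[keep, , drop = FALSE])
  if (!is.null(cohort$latents))
    out$latents <- cohort$latents[keep, , drop = FALSE]
  out
}
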