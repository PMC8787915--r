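#' Hippocampal-to-cortical volume ratio
#'
#' @param hippocampal_volume hippocampal volume(s) in mm^3 (positive).
#' @param cortical_total_volume cortical total volume(s) in mm^3 (positive).
#' @return HV:CTV ratio(s), dimensionless.
#' @export
#' @examples
#' compute_ratio(4000, 400000)  # 0.01
compute_ratio <- function(hippocampal_volume, cortical_total_volume) {
  if (any(hippocampal_volume <= 0, na.rm = TRUE) ||
      any(cortical_total_volume <= 0, na.rm = TRUE))
    abort("volumes must be positive", "atnprog_volume_error")
  hippocampal_volume / cortical_total_volume
}

#' Atrophy-based AD subtypes from the HV:CTV ratio
#'
#' Subjects with a ratio strictly above the within-sample 75th percentile
#' are labelled hippocampal-sparing (HpSp), strictly below the 25th
#' percentile limbic-predominant (LP), and the rest typical AD (tAD).
#' Percentiles use linear interpolation between order statistics
#' (`quantile` type 7); subjects equal to a boundary fall to tAD (strict
#' inequalities). Reference thresholds from an external sample may be
#' supplied instead.
#'
#' @param ratios numeric HV:CTV ratios (at least 4 subjects).
#' @param thresholds optional length-2 vector (25th, 75th percentile ratio
#'   values) overriding the within-sample percentiles.
#' @param subject_ids optional ids for the output table.
#' @return data frame of class `subtype_assignment` with `subject_id`,
#'   `hv_ctv_ratio`, `subtype` (factor HpSp/LP/tAD); attribute
#'   `thresholds` records the cuts used.
#' @export
#' @examples
#' assign_subtypes(c(1, 2, 3, 4))$subtype  # LP, tAD, tAD, HpSp
assign_subtypes <- function(ratios, thresholds = NULL, subject_ids = NULL) {
  if (length(ratios) < 4L)
    abort("subtyping needs at least 4 subjects", "atnprog_config_error")
  if (any(!is.finite(ratios)) || any(ratios <= 0))
    abort("ratios must be finite and positive", "atnprog_volume_error")
  if (is.null(thresholds))
    thresholds <- unname(quantile(ratios, c(0.25, 0.75), type = 7))
  if (thresholds[1] == thresholds[2] || all(ratios == ratios[1]))
    warning("degenerate ratio distribution; all subjects labelled tAD")
  subtype <- factor(rep("tAD", length(ratios)),
                    levels = c("HpSp", "LP", "tAD"))
  subtype[ratios > thresholds[2]] <- "HpSp"
  subtype[ratios < thresholds[1]] <- "LP"
  out <- data.frame(
    subject_id = subject_ids %||% paste0("S", seq_along(ratios)),
    hv_ctv_ratio = ratios, subtype = subtype)
  attr(out, "thresholds") <- thresholds
  class(out) <- c("subtype_assignment", class(out))
  out
}

#' Association between atrophy subtypes and progression phenotypes
#'
#' Builds the 3x2 subtype-by-phenotype contingency table (all three
#' canonical subtype levels retained) and applies the Pearson chi-square
#' test from [chi_square()]. Empty subtype rows propagate the margin error.
#'
#' @param subtypes a `subtype_assignment` (or factor with levels
#'   HpSp/LP/tAD).
#' @param phenotypes per-subject phenotype labels (factor MD/FD), aligned
#'   by `subject_id` when both carry ids.
#' @return a `contingency_result` with the subtype-by-phenotype table.
#' @export
associate_subtypes <- function(subtypes, phenotypes) {
  if (is.data.frame(subtypes)) {
    st <- subtypes$subtype
    ids <- subtypes$subject_id
  } else {
    st <- subtypes
    ids <- NULL
  }
  if (is.data.frame(phenotypes)) {
    if (!is.null(ids)) {
      if (!setequal(ids, phenotypes$subject_id))
        abort("subtype and phenotype label sets cover different subjects",
              "atnprog_alignment_error")
      phenotypes <- phenotypes$phenotype[match(ids, phenotypes$subject_id)]
    } else phenotypes <- phenotypes$phenotype
  }
  if (length(st) != length(phenotypes))
    abort("subtype and phenotype label sets cover different subjects",
          "atnprog_alignment_error")
  tab <- table(subtype = factor(st, levels = c("HpSp", "LP", "tAD")),
               phenotype = phenotypes)
  chi_square(unclass(tab))
}
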