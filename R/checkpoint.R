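#' Save / load a PENet model checkpoint
#'
#' Persists the model in R's native serialisation (`.rds`) with a JSON
#' sidecar describing the architecture specification, so a checkpoint can
#' be audited and reproduced without deserialising it.
#'
#' @param model a `penet_model`.
#' @param path checkpoint path (`.rds`; the sidecar gets `.json` appended).
#' @return `path`, invisibly.
#' @export
save_penet <- function(model, path) {
  stopifnot(inherits(model, "penet_model"))
  saveRDS(model, path)
  side <- unclass(model$spec)
  side$trained <- model$trained
  side$parameter_count <- penet_param_count(model$spec)$total
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname save_penet
#' @export
load_penet <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "penet_model"))
  model
}

#' Plot ROC curves of an ablation run
#'
#' One ROC curve per biomarker combination, with the chance diagonal.
#'
#' @param x an `atn_ablation`.
#' @param ... further arguments to [graphics::plot()].
#' @return the input, invisibly.
#' @export
#' @importFrom graphics abline legend lines plot
plot_roc <- function(x, ...) {
  stopifnot(inherits(x, "atn_ablation"))
  plot(NA, xlim = c(0, 1), ylim = c(0, 1), xlab = "False positive rate",
       ylab = "True positive rate", ...)
  abline(0, 1, lty = 3, col = "grey50")
  cols <- seq_along(x$results) + 1L
  for (i in seq_along(x$results)) {
    r <- x$results[[i]]
    lines(r$roc$fpr, r$roc$tpr, col = cols[i], lwd = 2)
  }
  legend("bottomright",
         legend = sprintf("%s (AUC %.2f)",
                          vapply(x$results, `[[`, character(1), "combination"),
                          vapply(x$results, `[[`, numeric(1), "auc")),
         col = cols, lwd = 2, bty = "n")
  invisible(x)
}

#' Per-region phantom intensity differences between phenotypes
#'
#' Qualitative stand-in for voxelwise atrophy contrasts: mean phantom
#' intensity inside the hippocampus-like and cortex-like regions per
#' phenotype group, with the group difference. Only meaningful for
#' generated cohorts, whose region masks are known.
#'
#' @param cohort an `atn_cohort` with volumes.
#' @param labels two-level per-subject labels (default: `true_class`).
#' @return data frame with region, per-group means, and difference.
#' @export
region_mean_differences <- function(cohort, labels = cohort$true_class) {
  stopifnot(!is.null(cohort$volumes))
  labels <- droplevels(as.factor(labels))
  stopifnot(nlevels(labels) == 2L)
  masks <- phantom_masks(dim(cohort$volumes[[1]]))
  out <- lapply(names(masks), function(rg) {
    m <- masks[[rg]]
    vals <- vapply(cohort$volumes, function(v) mean(v[m]), numeric(1))
    g <- vapply(split(vals, labels), mean, numeric(1))
    data.frame(region = rg, group1 = names(g)[1], mean1 = g[[1]],
               group2 = names(g)[2], mean2 = g[[2]],
               difference = g[[1]] - g[[2]])
  })
  do.call(rbind, out)
}
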