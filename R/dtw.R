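#' Dynamic time warping distance between two score sequences
#'
#' Classic DTW dynamic program with local cost \eqn{|a_i - b_j|}, step
#' pattern \{(1,0), (0,1), (1,1)\} and no warping window (unconstrained
#' global alignment). The returned value is the unnormalised optimal
#' alignment cost; it is symmetric and equals 0 iff the sequences are
#' identical in values and length.
#'
#' @param a,b non-empty finite numeric sequences.
#' @return non-negative alignment cost.
#' @export
#' @examples
#' dtw_distance(c(3, 1, 4), c(3, 1, 4))  # 0
#' dtw_distance(c(0, 0), c(1, 1))        # 2
dtw_distance <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L)
    abort("DTW requires non-empty sequences", "atnprog_length_error")
  if (anyNA(a) || anyNA(b))
    abort("DTW input contains missing values; drop or handle upstream",
          "atnprog_missing_data_error")
  if (!all(is.finite(a)) || !all(is.finite(b)))
    abort("DTW input must be finite", "atnprog_missing_data_error")
  cpp_dtw(as.numeric(a), as.numeric(b))
}

#' Pairwise DTW distance matrix for a set of trajectories
#'
#' Computes all pairwise [dtw_distance()] values (upper triangle once, by
#' symmetry). Subjects whose trajectory contains any missing visit are
#' dropped with a warning, matching the analysis rule that clustering
#' requires complete series.
#'
#' @param trajectories numeric matrix, subjects in rows, visits in columns;
#'   or a cohort `trajectories` list with a `scores` element.
#' @return symmetric non-negative matrix with zero diagonal; attribute
#'   `metric` is `"dtw"`, rownames/colnames are subject identifiers when
#'   available.
#' @export
pairwise_dtw <- function(trajectories) {
  x <- if (is.list(trajectories) && !is.data.frame(trajectories))
    trajectories$scores else as.matrix(trajectories)
  if (nrow(x) < 2L)
    abort("pairwise DTW needs at least 2 subjects", "atnprog_length_error")
  bad <- apply(x, 1L, anyNA)
  if (any(bad)) {
    warning(sprintf("dropping %d subject(s) with missing visits", sum(bad)))
    x <- x[!bad, , drop = FALSE]
  }
  d <- cpp_pairwise_dtw(x)
  dimnames(d) <- list(rownames(x), rownames(x))
  attr(d, "metric") <- "dtw"
  d
}
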