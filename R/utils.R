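#' Derive a per-stage seed from a global seed
#'
#' Deterministically fans a global integer seed out to named analysis stages,
#' so each stage's random stream is reproducible independently of execution
#' order. A small keyed polynomial hash of the stage name is mixed into the
#' seed; results stay inside the 32-bit integer range.
#'
#' @param seed integer global seed.
#' @param stage character stage name.
#' @return an integer seed.
#' @export
#' @examples
#' derive_seed(1, "cluster")
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  chars <- utf8ToInt(stage)
  h <- 0
  for (ch in chars) h <- (h * 131 + ch) %% 2147483647
  as.integer((abs(seed) %% 2147483647 * 48271 + h) %% 2147483647)
}

# Stop with a classed condition so callers can distinguish error families.
abort <- function(msg, class) {
  stop(structure(class = c(class, "atnprog_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Adjusted Rand index between two partitions (delegates to mclust).
ari <- function(a, b) mclust::adjustedRandIndex(a, b)
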