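#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnorm runif rbinom rmultinom rnbinom quantile sd var
#'   cor pt qt aggregate complete.cases predict rgamma median
#' @importFrom utils head
NULL

# Internal: stopifnot-style check with a formatted message.
check_that <- function(cond, msg, ...) {
  if (!isTRUE(cond)) stop(sprintf(msg, ...), call. = FALSE)
  invisible(TRUE)
}

# Internal: min-max scale a numeric vector to [0, 1].
# A constant vector maps to all zeros (degenerate range).
minmax01 <- function(x) {
  rng <- range(x)
  if (rng[2] - rng[1] < .Machine$double.eps) return(rep(0, length(x)))
  (x - rng[1]) / (rng[2] - rng[1])
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labellings of the same items,
#' used to score recovered cASV partitions against the ground-truth
#' ASV-to-taxon map.
#'
#' @param a,b vectors of cluster labels of equal length.
#' @return a single number in (-1, 1]; 1 means identical partitions.
#' @export
ari <- function(a, b) {
  check_that(length(a) == length(b), "partitions must have equal length")
  mclust::adjustedRandIndex(a, b)
}
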