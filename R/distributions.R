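#' @include AllClasses.R
NULL

#' Validate a discrete probability distribution
#'
#' Distributions over a symbol alphabet are plain named numeric vectors:
#' names are the support, values the probability mass. This checks the
#' invariants every distribution in the package obeys.
#'
#' @param d named numeric vector.
#' @param tol tolerance on the total mass.
#' @return `d`, invisibly, after validation.
#' @export
assertDistribution <- function(d, tol = 1e-9) {
  if (!is.numeric(d) || is.null(names(d)) || length(d) == 0L)
    stop("a distribution must be a non-empty named numeric vector")
  if (anyDuplicated(names(d))) stop("distribution support has duplicated symbols")
  if (any(d < 0)) stop("distribution has negative mass")
  if (abs(sum(d) - 1) > tol)
    stop(sprintf("distribution mass sums to %.12f, not 1", sum(d)))
  invisible(d)
}

#' Information content (surprisal) of a symbol under a distribution
#'
#' Returns the surprisal \eqn{-\log_2 p(s)} in bits. A peak of information
#' content marks a surprising observation; runs of low values mark
#' statistically coherent stretches of a stream.
#'
#' @param d named numeric probability vector.
#' @param symbol a symbol in the support of `d`.
#' @return non-negative surprisal in bits.
#' @export
#' @examples
#' informationContent(c(a = 0.25, b = 0.75), "a")  # 2 bits
informationContent <- function(d, symbol) {
  assertDistribution(d)
  if (!symbol %in% names(d))
    stop(sprintf("symbol '%s' is not in the support of the distribution", symbol))
  p <- unname(d[[symbol]])
  if (p == 0)
    stop(sprintf("symbol '%s' has zero mass; train with smoothing (k > 0) to assign residual mass", symbol))
  -log2(p)
}

#' Shannon entropy of a distribution, in bits
#'
#' Entropy quantifies the uncertainty of a predictive distribution; it is 0
#' for a point mass and `log2(length(d))` for the uniform distribution.
#'
#' @param d named numeric probability vector.
#' @return entropy in bits.
#' @export
#' @examples
#' entropyBits(c(a = 0.5, b = 0.25, c = 0.25))  # 1.5 bits
entropyBits <- function(d) {
  assertDistribution(d)
  p <- d[d > 0]
  -sum(p * log2(p))
}
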