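#' @include AllClasses.R
NULL

# Normalize a stream to a data.frame with columns symbol, onset_ms.
# Accepts a character vector (onsets become NA) or a data.frame already in
# that shape; a `viewpoint` argument selects among several symbol columns.
.asStream <- function(x, viewpoint = NULL) {
  if (is.character(x)) {
    return(data.frame(symbol = x, onset_ms = rep(NA_real_, length(x)),
                      stringsAsFactors = FALSE))
  }
  if (is.data.frame(x)) {
    if (!is.null(viewpoint) && viewpoint %in% names(x)) {
      sym <- x[[viewpoint]]
    } else if ("symbol" %in% names(x)) {
      sym <- x$symbol
    } else {
      stop("stream data.frame needs a 'symbol' column (or the named viewpoint column)")
    }
    onset <- if ("onset_ms" %in% names(x)) as.numeric(x$onset_ms) else rep(NA_real_, nrow(x))
    if (any(!is.na(onset)) && any(diff(onset[!is.na(onset)]) < 0))
      stop("onsets must be non-decreasing within a stream")
    if (any(!is.na(onset) & onset < 0)) stop("onsets must be non-negative")
    return(data.frame(symbol = as.character(sym), onset_ms = onset,
                      stringsAsFactors = FALSE))
  }
  stop("a stream must be a character vector or a data.frame")
}

.asCorpus <- function(corpus, viewpoint = NULL) {
  if (is.character(corpus) || is.data.frame(corpus)) corpus <- list(corpus)
  if (!is.list(corpus) || length(corpus) == 0L) stop("corpus must be a non-empty list of streams")
  lapply(corpus, .asStream, viewpoint = viewpoint)
}

#' Derive a reproducible sub-seed for a named stage
#'
#' One top-level seed is expanded into independent per-stage seeds by hashing
#' the stage name, so pipeline stages can be re-run in isolation without
#' disturbing each other's random streams.
#'
#' @param seed integer master seed.
#' @param stage character stage name.
#' @return an integer seed below 2^31.
#' @export
stageSeed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

.binIndex <- function(t_ms, quantum_ms) as.integer(floor(t_ms / quantum_ms)) + 1L
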