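#' @import methods
NULL

KEY_SEP <- "\x1f"

.key <- function(symbols) paste(symbols, collapse = KEY_SEP)

# storage key for a prediction context; the empty (unigram) context gets the
# bare separator because environments cannot hold an empty name
.ctxKey <- function(context) if (length(context) == 0L) KEY_SEP else .key(context)
.unkey <- function(key) {
  if (identical(key, "")) character(0) else strsplit(key, KEY_SEP, fixed = TRUE)[[1L]]
}

#' Markov transition model over a symbol alphabet
#'
#' Holds exact n-gram transition counts for one viewpoint at one hierarchy
#' level, together with the declared alphabet and an additive smoothing
#' constant. Counts are kept separately for every context length from 0
#' (unigram) up to `order`, so prediction can back off to shorter contexts
#' when a context has never been observed.
#'
#' @slot order maximum context length (positive integer).
#' @slot viewpoint name of the feature stream the model was trained on.
#' @slot level hierarchy level of the symbols (0 = surface).
#' @slot alphabet character vector of all symbols the model predicts over.
#' @slot counts list with one element per context length 0..order; each is a
#'   named list mapping a context key to a named numeric vector of
#'   continuation counts.
#' @slot smoothing name of the smoothing scheme (currently `"add-k"`).
#' @slot k additive smoothing constant applied over the declared alphabet.
#' @slot nStreams number of (non-empty) training streams.
#' @exportClass TransitionModel
setClass("TransitionModel",
  representation(
    order = "integer",
    viewpoint = "character",
    level = "integer",
    alphabet = "character",
    counts = "list",
    smoothing = "character",
    k = "numeric",
    nStreams = "integer"
  ),
  prototype(
    order = 1L, viewpoint = "default", level = 0L,
    alphabet = character(0), counts = list(),
    smoothing = "add-k", k = 1, nStreams = 0L
  )
)

setValidity("TransitionModel", function(object) {
  msgs <- character(0)
  if (length(object@order) != 1L || object@order < 1L)
    msgs <- c(msgs, "order must be a single positive integer")
  if (length(object@counts) != object@order + 1L)
    msgs <- c(msgs, "counts must have one table per context length 0..order")
  if (object@k < 0) msgs <- c(msgs, "smoothing constant k must be >= 0")
  for (tab in object@counts) {
    for (cts in tab) {
      if (any(cts < 0)) msgs <- c(msgs, "negative transition count")
      if (!all(names(cts) %in% object@alphabet))
        msgs <- c(msgs, "continuation symbol outside declared alphabet")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Layered chunk memory over a corpus of symbol streams
#'
#' The result of repeated train/chunk/label passes: level 0 holds the surface
#' streams, each higher level holds the label streams of the chunks found one
#' level below. Registries record, per level, which member sequence each
#' label expands to, so the surface can always be reconstructed exactly.
#'
#' @slot levels list of levels; each level is a list of streams, and each
#'   stream is a data.frame with columns `symbol` and `onset_ms`.
#' @slot registries list with one element per built level transition; each is
#'   a named list mapping a level-(k+1) label to the character vector of its
#'   level-k members.
#' @slot models list of [TransitionModel-class] objects, one per level.
#' @slot theta chunk-boundary threshold in bits.
#' @slot maxLen maximum buffer length before a forced flush.
#' @slot maxDepth,maxAlphabet the configured caps.
#' @exportClass HierarchicalMemory
setClass("HierarchicalMemory",
  representation(
    levels = "list",
    registries = "list",
    models = "list",
    theta = "numeric",
    maxLen = "integer",
    maxDepth = "integer",
    maxAlphabet = "numeric"
  )
)

setValidity("HierarchicalMemory", function(object) {
  msgs <- character(0)
  if (length(object@levels) < 1L) msgs <- c(msgs, "memory must hold at least the surface level")
  if (length(object@registries) != length(object@levels) - 1L)
    msgs <- c(msgs, "one registry is required per built level transition")
  nLev <- length(object@levels)
  if (nLev > 1L) {
    for (d in seq_len(nLev - 1L)) {
      reg <- object@registries[[d]]
      for (i in seq_along(object@levels[[d + 1L]])) {
        upper <- object@levels[[d + 1L]][[i]]$symbol
        if (!all(upper %in% names(reg))) {
          msgs <- c(msgs, sprintf("level %d stream %d has unregistered labels", d, i))
          next
        }
        expanded <- unlist(reg[upper], use.names = FALSE)
        if (!identical(expanded, object@levels[[d]][[i]]$symbol))
          msgs <- c(msgs, sprintf("level %d stream %d does not expand to the level below", d, i))
      }
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Per-transition inter-onset-interval densities on a fixed time grid
#'
#' For every observed (context, symbol) transition the model keeps a
#' histogram of the inter-onset interval (IOI) between the last context event
#' and the continuation event, binned on a half-open grid of `quantumMs`
#' milliseconds. Together with a [TransitionModel-class] this forms a Markov
#' renewal view of an event stream: the chain says what comes next, the
#' holding-time densities say when.
#'
#' @slot quantumMs bin width in milliseconds (half-open bins `[t, t+q)`).
#' @slot horizonMs extent of the grid; IOIs at or beyond it are not counted.
#' @slot level hierarchy level the model was trained at.
#' @slot order context length used when keying transitions.
#' @slot table named list mapping `(context, symbol)` keys to per-bin counts.
#' @slot marginal per-bin IOI counts pooled over all transitions.
#' @slot nObserved number of IOIs counted; nDropped number beyond horizon.
#' @exportClass TemporalModel
setClass("TemporalModel",
  representation(
    quantumMs = "integer",
    horizonMs = "integer",
    level = "integer",
    order = "integer",
    table = "list",
    marginal = "numeric",
    nObserved = "integer",
    nDropped = "integer"
  )
)

setValidity("TemporalModel", function(object) {
  msgs <- character(0)
  if (object@quantumMs < 1L) msgs <- c(msgs, "quantumMs must be >= 1")
  nb <- object@horizonMs %/% object@quantumMs
  if (length(object@marginal) != nb)
    msgs <- c(msgs, "marginal histogram length must equal the number of grid bins")
  for (cts in object@table) {
    if (length(cts) != nb) msgs <- c(msgs, "per-transition histogram has wrong length")
    if (any(cts < 0)) msgs <- c(msgs, "negative IOI count")
  }
  if (length(msgs)) msgs else TRUE
})

#' Additive multi-level metrical expectation profile
#'
#' Onset-expectation strength per time bin, per hierarchy level, anchored at
#' a reference event at time zero. The combined profile is the exact sum of
#' the per-level rows: coinciding expectations from several levels add up,
#' which is what makes metrically strong positions strong.
#'
#' @slot quantumMs,horizonMs the time grid.
#' @slot perLevel numeric matrix, one row per level, one column per bin;
#'   entries are expected onset mass per bin contributed by that level.
#' @slot combined numeric vector, the column sums of `perLevel`.
#' @slot binStartMs start time of each bin.
#' @exportClass ExpectationProfile
setClass("ExpectationProfile",
  representation(
    quantumMs = "integer",
    horizonMs = "integer",
    perLevel = "matrix",
    combined = "numeric",
    binStartMs = "numeric"
  )
)

setValidity("ExpectationProfile", function(object) {
  msgs <- character(0)
  if (any(object@perLevel < -1e-12)) msgs <- c(msgs, "expectation strengths must be non-negative")
  if (max(abs(object@combined - colSums(object@perLevel))) > 1e-9)
    msgs <- c(msgs, "combined profile must equal the per-level sum")
  if (length(msgs)) msgs else TRUE
})

#' Tapping record from the entrainment simulator
#'
#' @slot tapTimesMs strictly increasing tap times.
#' @slot phaseErrorsMs signed error of each tap against the nearest stimulus
#'   onset (tap minus onset).
#' @slot periodMs the period the tapper used.
#' @slot gain the phase-correction gain in `[0, 1]`.
#' @exportClass TapRecord
setClass("TapRecord",
  representation(
    tapTimesMs = "numeric",
    phaseErrorsMs = "numeric",
    periodMs = "numeric",
    gain = "numeric"
  )
)

setValidity("TapRecord", function(object) {
  msgs <- character(0)
  if (length(object@tapTimesMs) > 1L && any(diff(object@tapTimesMs) <= 0))
    msgs <- c(msgs, "tap times must be strictly increasing")
  if (length(object@phaseErrorsMs) != length(object@tapTimesMs))
    msgs <- c(msgs, "one phase error is required per tap")
  if (length(msgs)) msgs else TRUE
})

#' A metrical structure as a point in a quality-dimension space
#'
#' Coordinates are the subdivision ratios of the metrical hierarchy, one
#' quality dimension per level; an additively grouped level (such as the
#' 2+2+3 of 7/8) occupies one dimension per group, holding the normalized
#' group-length vector. An optional tempo dimension carries the basic unit in
#' milliseconds; projecting it away abstracts the meter from tempo.
#'
#' @slot coordinates named numeric vector of coordinate values.
#' @slot domains character vector, same length, assigning each dimension to a
#'   domain; distance is Euclidean within a domain and city-block across
#'   domains.
#' @exportClass MeterPoint
setClass("MeterPoint",
  representation(coordinates = "numeric", domains = "character")
)

setValidity("MeterPoint", function(object) {
  msgs <- character(0)
  if (length(object@coordinates) != length(object@domains))
    msgs <- c(msgs, "each coordinate needs a domain assignment")
  if (is.null(names(object@coordinates)) || anyDuplicated(names(object@coordinates)))
    msgs <- c(msgs, "coordinates must have unique names")
  if (any(!is.finite(object@coordinates))) msgs <- c(msgs, "coordinates must be finite")
  if (length(msgs)) msgs else TRUE
})

#' Statistical diagnosis of a sequence of performance timings
#'
#' @slot label one of `"groove"`, `"inconsistent_error"`, `"tempo_change"`.
#' @slot offsetMs largest per-position mean deviation magnitude.
#' @slot dispersionMs pooled within-position standard deviation.
#' @slot trend Spearman rank correlation of per-performance deviation
#'   magnitude against performance index.
#' @exportClass TimingDiagnosis
setClass("TimingDiagnosis",
  representation(
    label = "character",
    offsetMs = "numeric",
    dispersionMs = "numeric",
    trend = "numeric"
  )
)

setValidity("TimingDiagnosis", function(object) {
  if (length(object@label) != 1L ||
      !object@label %in% c("groove", "inconsistent_error", "tempo_change"))
    "label must be exactly one of groove, inconsistent_error, tempo_change"
  else TRUE
})
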