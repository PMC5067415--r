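#' @include transitions.R
NULL

#' Learn per-transition inter-onset-interval densities
#'
#' For every transition (context -> symbol) in the timed corpus, the
#' inter-onset interval between the context's last event and the
#' continuation event is accumulated into a histogram on a half-open grid of
#' `quantum_ms` milliseconds. The default 20 ms quantum is the finest
#' temporal resolution at which listeners reliably order two onsets, so a
#' finer grid buys nothing perceptually.
#'
#' @param model the [TransitionModel-class] whose contexts key the table.
#' @param corpus a timed stream or list of timed streams (data.frames with
#'   `symbol` and `onset_ms`).
#' @param quantum_ms grid resolution in ms (default 20).
#' @param horizon_ms grid extent in ms; IOIs at or beyond it are dropped
#'   with a warning (default 4000).
#' @return a [TemporalModel-class].
#' @export
observeTiming <- function(model, corpus, quantum_ms = 20L, horizon_ms = 4000L) {
  quantum_ms <- as.integer(quantum_ms)
  horizon_ms <- as.integer(horizon_ms)
  if (quantum_ms < 1L) stop("quantum_ms must be >= 1")
  nb <- horizon_ms %/% quantum_ms
  streams <- .asCorpus(corpus, viewpoint = model@viewpoint)
  tab <- new.env(parent = emptyenv())
  marginal <- numeric(nb)
  nObs <- 0L; nDrop <- 0L
  for (s in streams) {
    if (any(is.na(s$onset_ms))) stop("observeTiming needs time-stamped events (onset_ms)")
    n <- nrow(s)
    if (n < 2L) next
    for (i in 2:n) {
      ioi <- s$onset_ms[i] - s$onset_ms[i - 1L]
      if (ioi < 0) stop(sprintf("negative inter-onset interval at position %d", i))
      bin <- .binIndex(ioi, quantum_ms)
      if (bin > nb) { nDrop <- nDrop + 1L; next }
      ctx <- s$symbol[max(1L, i - model@order):(i - 1L)]
      key <- paste(.key(ctx), s$symbol[i], sep = KEY_SEP)
      cur <- tab[[key]]
      if (is.null(cur)) cur <- numeric(nb)
      cur[bin] <- cur[bin] + 1
      tab[[key]] <- cur
      marginal[bin] <- marginal[bin] + 1
      nObs <- nObs + 1L
    }
  }
  if (nDrop > 0L)
    warning(sprintf("%d IOI(s) at or beyond the %d ms horizon were not counted", nDrop, horizon_ms))
  new("TemporalModel",
      quantumMs = quantum_ms, horizonMs = horizon_ms,
      level = model@level, order = model@order,
      table = as.list(tab), marginal = marginal,
      nObserved = nObs, nDropped = nDrop)
}

setMethod("show", "TemporalModel", function(object) {
  cat(sprintf(
    "TemporalModel: %d ms grid over %d ms (%d bins)\n  %d transition densities from %d observed IOIs (level %d)\n",
    object@quantumMs, object@horizonMs, length(object@marginal),
    length(object@table), object@nObserved, object@level))
})

.temporalKey <- function(context, symbol) paste(.key(context), symbol, sep = KEY_SEP)

# Raw per-bin counts for (context, symbol); NULL if the pair was never timed.
.temporalCounts <- function(tm, context, symbol) {
  tm@table[[.temporalKey(as.character(context), symbol)]]
}

#' Inter-onset-interval density for one transition
#'
#' Returns the learned density over the grid for the given transition. With
#' `smooth = TRUE` (the default) every bin keeps a small mass floor
#' (`floor_mass` spread over the grid) so that surprisal stays finite for
#' never-observed timings, and a never-observed pair returns the uniform
#' density. With `smooth = FALSE` an unseen pair is an error.
#'
#' @param tm a [TemporalModel-class].
#' @param context character vector of context symbols.
#' @param symbol continuation symbol.
#' @param smooth logical (default `TRUE`).
#' @param floor_mass total probability mass distributed uniformly over the
#'   grid as a floor (default 1e-4).
#' @return numeric density vector over the grid bins, summing to 1.
#' @export
temporalDistribution <- function(tm, context, symbol, smooth = TRUE, floor_mass = 1e-4) {
  cts <- .temporalCounts(tm, context, symbol)
  nb <- length(tm@marginal)
  if (is.null(cts)) {
    if (!smooth)
      stop(sprintf("transition (%s -> %s) has no timing observations; enable smoothing",
                   paste(context, collapse = " "), symbol))
    return(rep(1 / nb, nb))
  }
  d <- cts / sum(cts)
  if (smooth) d <- (1 - floor_mass) * d + floor_mass / nb
  d
}

#' Marginal inter-onset-interval density of a temporal model
#' @inheritParams temporalDistribution
#' @return numeric density vector over the grid bins.
#' @export
marginalIOIDensity <- function(tm, smooth = FALSE, floor_mass = 1e-4) {
  nb <- length(tm@marginal)
  if (sum(tm@marginal) == 0) return(rep(1 / nb, nb))
  d <- tm@marginal / sum(tm@marginal)
  if (smooth) d <- (1 - floor_mass) * d + floor_mass / nb
  d
}

#' Time axis of a temporal model or profile grid
#' @param tm a [TemporalModel-class].
#' @return numeric vector of bin start times in ms.
#' @export
gridTimes <- function(tm) (seq_along(tm@marginal) - 1L) * tm@quantumMs

#' Instantaneous symbol distribution at a time since the last event
#'
#' Slices across the per-symbol temporal densities at time `t`: the mass of
#' each symbol is its sequence probability given the context multiplied by
#' its IOI density at `t`'s bin, renormalized over the alphabet. When every
#' product is zero the sequence distribution alone is returned. This is how
#' a what-predictor and a when-predictor fuse into "what, right now".
#'
#' @param tm a [TemporalModel-class].
#' @param what_model the matching [TransitionModel-class].
#' @param context character vector of context symbols.
#' @param t_ms non-negative time since the last event, below the horizon.
#' @param smooth logical, smooth both factors (default `TRUE`).
#' @return named numeric distribution over the alphabet.
#' @export
instantaneousDistribution <- function(tm, what_model, context, t_ms, smooth = TRUE) {
  if (t_ms < 0) stop("t_ms must be non-negative")
  bin <- .binIndex(t_ms, tm@quantumMs)
  if (bin > length(tm@marginal)) stop("t_ms is beyond the model horizon")
  pWhat <- predictNext(what_model, context, smooth = smooth)
  w <- vapply(names(pWhat), function(s) {
    cts <- .temporalCounts(tm, context, s)
    dens <- if (is.null(cts) && !smooth) 0 else
      temporalDistribution(tm, context, s, smooth = smooth)[bin]
    pWhat[[s]] * dens
  }, numeric(1))
  if (sum(w) <= 0) {
    message("all what-by-when products are zero at t; falling back to the sequence distribution")
    return(pWhat)
  }
  assertDistribution(w / sum(w))
}

#' Joint what-and-when surprisal of each event in a timed stream
#'
#' For every event beyond the first, the information content (bits) of
#' observing that symbol at that inter-onset interval:
#' `-log2( P(symbol | context) * P(IOI bin | context, symbol) )`.
#' Spikes mark temporal jolts — events whose timing (or identity) the model
#' did not expect, such as the shortened cycle a listener trained on 4/4
#' meets in 7/8.
#'
#' @param tm a [TemporalModel-class].
#' @param what_model the matching [TransitionModel-class].
#' @param stream a timed stream data.frame.
#' @return numeric vector of surprisal values, `NA` for the first event.
#' @export
eventSurprisal <- function(tm, what_model, stream) {
  s <- .asStream(stream, viewpoint = what_model@viewpoint)
  n <- nrow(s)
  out <- rep(NA_real_, n)
  if (n < 2L) return(out)
  for (i in 2:n) {
    ctx <- s$symbol[max(1L, i - what_model@order):(i - 1L)]
    pWhat <- predictNext(what_model, ctx, smooth = TRUE)
    ioi <- s$onset_ms[i] - s$onset_ms[i - 1L]
    bin <- .binIndex(ioi, tm@quantumMs)
    dens <- temporalDistribution(tm, ctx, s$symbol[i], smooth = TRUE)
    pBin <- if (bin > length(dens)) min(dens[dens > 0]) else dens[bin]
    p <- pWhat[[s$symbol[i]]] * pBin
    out[i] <- -log2(p)
  }
  out
}
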