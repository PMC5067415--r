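#' @include profile.R
NULL

#' Dominant period of an expectation profile
#'
#' The time of the earliest strict local maximum of the combined strength
#' that reaches `frac` of the global maximum (earliest-time tie-breaking).
#' For a profile learned from a periodic stream this is the basic period a
#' tapper would lock to.
#'
#' @param profile an [ExpectationProfile-class].
#' @param frac fraction of the global maximum a peak must reach (default 0.5).
#' @return period in ms.
#' @export
profilePeriod <- function(profile, frac = 0.5) {
  s <- profile@combined
  thr <- frac * max(s)
  peaks <- profilePeaks(profile, frac)
  if (length(peaks) == 0L) stop("profile has no peak above the threshold")
  peaks[1L]
}

#' Peak times of an expectation profile
#'
#' Strict local maxima of the combined strength at or above `frac` of its
#' global maximum. A run of equal values counts once, at its earliest bin.
#'
#' @inheritParams profilePeriod
#' @return numeric vector of peak bin start times in ms.
#' @export
profilePeaks <- function(profile, frac = 0.5) {
  s <- profile@combined
  n <- length(s)
  thr <- frac * max(s)
  left <- c(-Inf, s[-n])
  right <- c(s[-1L], -Inf)
  idx <- which(s >= thr & s > left & s >= right)
  profile@binStartMs[idx]
}

#' Simulate entrainment (tapping) to an onset stream
#'
#' A minimal phase-correcting tapper: the period comes from the expectation
#' profile (or is given directly); the phase is anchored at the first
#' observed onset. Each subsequent prediction is the previous one advanced
#' by the period, corrected after every observed onset by
#' `gain * (observed - predicted)`. Taps are only emitted once two onsets
#' have been observed. With a correct period, the signed prediction error
#' contracts by a factor `(1 - gain)` per event.
#'
#' @param x an [ExpectationProfile-class] or a single numeric period in ms.
#' @param onsets_ms numeric vector of at least 3 stimulus onset times.
#' @param gain phase-correction gain in `[0, 1]`; 0 disables correction.
#' @return a [TapRecord-class]. Taps are the predicted times for onsets 3
#'   onward; `phaseErrors` are tap minus the nearest stimulus onset.
#' @export
entrain <- function(x, onsets_ms, gain = 0.5) {
  if (gain < 0 || gain > 1) stop("gain must lie in [0, 1]")
  onsets_ms <- as.numeric(onsets_ms)
  if (length(onsets_ms) < 3L) stop("at least two onsets must be observed before the first tap")
  if (any(diff(onsets_ms) <= 0)) stop("onsets must be strictly increasing")
  period <- if (is(x, "ExpectationProfile")) profilePeriod(x) else as.numeric(x)
  if (!is.finite(period) || period <= 0) stop("period must be positive")

  n <- length(onsets_ms)
  preds <- numeric(n - 1L)
  preds[1L] <- onsets_ms[1L] + period
  for (k in seq_len(n - 2L)) {
    err <- onsets_ms[k + 1L] - preds[k]
    preds[k + 1L] <- preds[k] + period + gain * err
  }
  taps <- preds[-1L]  # predictions for onsets 3..n
  phase <- vapply(taps, function(tp) tp - onsets_ms[which.min(abs(onsets_ms - tp))], numeric(1))
  new("TapRecord", tapTimesMs = taps, phaseErrorsMs = phase,
      periodMs = period, gain = gain)
}

setMethod("tapTimes", "TapRecord", function(object) object@tapTimesMs)
setMethod("phaseErrors", "TapRecord", function(object) object@phaseErrorsMs)

setMethod("show", "TapRecord", function(object) {
  cat(sprintf(
    "TapRecord: %d taps, period %.1f ms, gain %.2f\n  mean |phase error| %.2f ms (final %.2f ms)\n",
    length(object@tapTimesMs), object@periodMs, object@gain,
    mean(abs(object@phaseErrorsMs)),
    if (length(object@phaseErrorsMs)) abs(utils::tail(object@phaseErrorsMs, 1L)) else NA_real_))
})

#' Convert a tap record to a data.frame
#' @param x a [TapRecord-class].
#' @param row.names,optional,... ignored; present for the generic.
#' @return data.frame with `tap_ms` and `error_ms`.
#' @export
as.data.frame.TapRecord <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(tap_ms = x@tapTimesMs, error_ms = x@phaseErrorsMs)
}
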