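#' @include temporal.R chunking.R
NULL

# Expected-onset density per bin for one level, by propagating the Markov
# renewal dynamics forward from an anchor event at t = 0.
#
# State: mass over (symbol, time bin) pairs for "an event with this symbol
# occurred at this time". Each pass moves every frontier atom one event
# ahead: mass m at (s, t) spreads to (s', t + d) with weight
# P(s' | s) * f_{s -> s'}(d). The per-bin sums of all passes give the
# expected number of onsets in each bin — for a point-mass period p this is
# exactly unit mass at p, 2p, 3p, ...
.renewalDensity <- function(what_model, tm, anchor, n_bins, tol = 1e-4, max_pass = 256L) {
  syms <- what_model@alphabet
  nS <- length(syms)
  # frontier[s, j]: mass of an event with symbol s in time bin j, i.e. at
  # t in [(j-1)q, jq); the anchor event sits in bin 1 (t = 0)
  frontier <- matrix(0, nS, n_bins, dimnames = list(syms, NULL))
  frontier[names(anchor), 1L] <- anchor
  u <- numeric(n_bins)
  # precompute g[s, s'] = P(s'|s) * f_{s->s'} for pairs with temporal data
  dens <- list()
  for (s in syms) {
    pNext <- predictNext(what_model, s, smooth = FALSE)
    for (s2 in names(pNext)[pNext > 0]) {
      cts <- .temporalCounts(tm, s, s2)
      f <- if (is.null(cts) || sum(cts) == 0) {
        m <- marginalIOIDensity(tm)
        if (sum(m) == 0) next else m
      } else cts / sum(cts)
      dens[[paste(s, s2, sep = KEY_SEP)]] <- list(from = s, to = s2, g = pNext[[s2]] * f)
    }
  }
  if (length(dens) == 0L) return(u)
  for (pass in seq_len(max_pass)) {
    nxt <- matrix(0, nS, n_bins, dimnames = list(syms, NULL))
    for (tr in dens) {
      fr <- frontier[tr$from, ]
      nz <- which(fr > 0)
      if (length(nz) == 0L) next
      for (j in nz) {
        # an event in bin j followed by an IOI in bin d lands in bin j + d - 1
        reach <- n_bins - j + 1L
        if (reach < 1L) next
        idx <- seq_len(min(reach, n_bins))
        nxt[tr$to, j + idx - 1L] <- nxt[tr$to, j + idx - 1L] + fr[j] * tr$g[idx]
      }
    }
    u <- u + colSums(nxt)
    frontier <- nxt
    if (sum(nxt) < tol) break
  }
  u
}

#' Multi-level metrical expectation profile
#'
#' For each hierarchy level of a memory, propagates that level's Markov
#' renewal dynamics (its transition model plus its inter-onset densities)
#' forward from a reference event at time zero, giving the expected onset
#' mass per grid bin contributed by that level. The combined profile is the
#' plain, unweighted sum over levels: positions where several levels'
#' expectations coincide come out strong, which is the additive-cycle view
#' of metrical strength. The anchor state of each level is the empirical
#' distribution of its stream-initial symbols, so profiles are anchored at
#' the cycle start of the training streams.
#'
#' @param memory a [HierarchicalMemory-class] built from timed streams.
#' @param temporal_models optional list of [TemporalModel-class], one per
#'   level; by default they are fitted from the memory's own level streams.
#' @param quantum_ms,horizon_ms the profile grid (defaults 20 ms, 4000 ms).
#' @param level_weights optional non-negative weight per level (default all
#'   1, the plain additive combination).
#' @return an [ExpectationProfile-class].
#' @export
expectationProfile <- function(memory, temporal_models = NULL,
                               quantum_ms = 20L, horizon_ms = 4000L,
                               level_weights = NULL) {
  nLev <- nLevels(memory)
  if (is.null(temporal_models)) {
    temporal_models <- lapply(seq_len(nLev) - 1L, function(d)
      observeTiming(memory@models[[d + 1L]], memory@levels[[d + 1L]],
                    quantum_ms = quantum_ms, horizon_ms = horizon_ms))
  }
  if (length(temporal_models) != nLev)
    stop("one temporal model per level is required")
  if (is.null(level_weights)) level_weights <- rep(1, nLev)
  if (length(level_weights) != nLev || any(level_weights < 0))
    stop("level_weights must be one non-negative weight per level")
  nb <- as.integer(horizon_ms) %/% as.integer(quantum_ms)
  perLevel <- matrix(0, nLev, nb,
                     dimnames = list(paste0("level", seq_len(nLev) - 1L), NULL))
  for (d in seq_len(nLev)) {
    tm <- temporal_models[[d]]
    if (is.null(tm) || tm@nObserved == 0L) {
      warning(sprintf("level %d has no timing observations; skipped", d - 1L))
      next
    }
    inits <- vapply(memory@levels[[d]], function(s)
      if (nrow(s)) s$symbol[1L] else NA_character_, character(1))
    inits <- inits[!is.na(inits)]
    anchor <- table(inits) / length(inits)
    anchor <- stats::setNames(as.numeric(anchor), names(anchor))
    perLevel[d, ] <- level_weights[d] *
      .renewalDensity(memory@models[[d]], tm, anchor, nb)
  }
  new("ExpectationProfile",
      quantumMs = as.integer(quantum_ms), horizonMs = as.integer(horizon_ms),
      perLevel = perLevel, combined = colSums(perLevel),
      binStartMs = (seq_len(nb) - 1L) * as.integer(quantum_ms))
}

setMethod("combinedStrength", "ExpectationProfile", function(object) object@combined)

#' Per-level strengths of an expectation profile
#' @param profile an [ExpectationProfile-class].
#' @return matrix of strengths, one row per level.
#' @export
levelStrength <- function(profile) profile@perLevel

setMethod("show", "ExpectationProfile", function(object) {
  pk <- object@binStartMs[which.max(object@combined)]
  cat(sprintf(
    "ExpectationProfile: %d levels on a %d ms grid over %d ms\n  peak combined strength %.3f at t = %d ms\n",
    nrow(object@perLevel), object@quantumMs, object@horizonMs,
    max(object@combined), as.integer(pk)))
})

#' Convert an expectation profile to a data.frame
#' @param x an [ExpectationProfile-class].
#' @param row.names,optional,... ignored; present for the generic.
#' @return data.frame with `bin_start_ms`, `strength`, and one
#'   `level<k>` column per level.
#' @export
as.data.frame.ExpectationProfile <- function(x, row.names = NULL, optional = FALSE, ...) {
  out <- data.frame(bin_start_ms = x@binStartMs, strength = x@combined)
  for (d in seq_len(nrow(x@perLevel))) out[[rownames(x@perLevel)[d]]] <- x@perLevel[d, ]
  out
}

#' Detect loud rests: strongly expected beats with no event
#'
#' Flags every grid bin whose combined expectation strength is at least
#' `strength_threshold` but which contains no onset. Onsets are taken
#' relative to the first onset, matching the profile's anchoring at a cycle
#' start, so the detector is invariant under a global time shift of the
#' stimulus. Only bins up to the last onset are considered: a rest is only
#' "loud" while the rhythm is still going.
#'
#' @param profile an [ExpectationProfile-class].
#' @param onsets_ms numeric vector of stimulus onset times.
#' @param strength_threshold positive threshold; defaults to half the
#'   maximum combined strength (a strongly expected beat is one at least
#'   half as expected as the strongest).
#' @return numeric vector of flagged bin start times (ms relative to the
#'   first onset).
#' @export
detectLoudRests <- function(profile, onsets_ms,
                            strength_threshold = 0.5 * max(combinedStrength(profile))) {
  if (strength_threshold <= 0) stop("strength_threshold must be positive")
  if (length(onsets_ms) == 0L) stop("onsets_ms must be non-empty")
  rel <- sort(onsets_ms) - min(onsets_ms)
  onsetBins <- unique(.binIndex(rel, profile@quantumMs))
  lastBin <- max(onsetBins)
  strong <- which(profile@combined >= strength_threshold)
  flagged <- setdiff(strong[strong <= lastBin], onsetBins)
  profile@binStartMs[flagged]
}
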