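# Shared fixtures, built in code at test time.

# brute-force first-order transition counts by enumerating adjacent pairs
bruteCounts <- function(stream) {
  out <- list()
  if (length(stream) < 2L) return(out)
  for (i in 2:length(stream)) {
    a <- stream[i - 1L]; b <- stream[i]
    if (is.null(out[[a]])) out[[a]] <- numeric(0)
    out[[a]][b] <- if (is.na(out[[a]][b])) 1 else out[[a]][b] + 1
  }
  out
}

# model counts for a single-symbol context, as a plain named vector
modelCounts <- function(model, context_symbol) {
  cts <- model@counts[[2L]][[context_symbol]]
  if (is.null(cts)) numeric(0) else cts
}

# index of the grid bin containing time t
.binHit <- function(tm, t) floor(t / tm@quantumMs) + 1L

# an isochronous event stream of one repeated symbol
isoStream <- function(n, period_ms, symbol = "x", start_ms = 0) {
  data.frame(symbol = rep(symbol, n),
             onset_ms = start_ms + (seq_len(n) - 1L) * period_ms)
}

# a two-level memory built by hand: surface events every `p0` quanta, one
# chunk label spanning `span` surface events (period p0 * span quanta)
handMemory <- function(n_surface = 64L, quantum = 20L, p0 = 2L, span = 2L) {
  surf <- isoStream(n_surface, p0 * quantum)
  lab <- data.frame(symbol = rep("X", n_surface %/% span),
                    onset_ms = (seq_len(n_surface %/% span) - 1L) * p0 * span * quantum)
  registry <- list(X = rep("x", span))
  m0 <- trainTransitions(list(surf))
  m1 <- trainTransitions(list(lab))
  new("HierarchicalMemory",
      levels = list(list(surf), list(lab)),
      registries = list(registry),
      models = list(m0, m1),
      theta = 0, maxLen = 16L, maxDepth = 1L, maxAlphabet = Inf)
}

# canonical two-bar rock-beat onsets on an eighth grid: beats 1, 2, the
# anticipated ("pushed") third beat and beat 4 in bar one; all four beats in
# bar two. The mid-bar expectation of bar one is unrealized.
rockPattern <- function(unit_ms = 240) unit_ms * c(0, 2, 3, 6, 8, 10, 12, 14)

# deterministic 2+2+3 pattern (group starts only), n bars
sevenEightPattern <- function(n_bars = 4L, unit_ms = 240) {
  bar <- unit_ms * c(0, 2, 4)
  onsets <- as.vector(vapply(seq_len(n_bars) - 1L,
                             function(b) bar + b * 7 * unit_ms, numeric(3)))
  data.frame(symbol = rep(c("db", "bt", "mb"), n_bars), onset_ms = onsets)
}
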