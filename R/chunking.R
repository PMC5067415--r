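#' @include transitions.R
NULL

#' Chunk-boundary decision from two successive surprisal values
#'
#' A chunk boundary falls before the current symbol when its information
#' content rises above the previous symbol's by more than `theta` bits: a
#' jump in surprisal marks the start of a new statistically coherent group.
#' The rule is online — it needs no lookahead.
#'
#' @param ic_prev,ic_curr finite surprisal values in bits.
#' @param theta non-negative rise threshold in bits (default 0).
#' @return `TRUE` if a boundary falls before the current symbol.
#' @export
boundaryDecision <- function(ic_prev, ic_curr, theta = 0) {
  if (!is.finite(ic_prev) || !is.finite(ic_curr)) stop("surprisal values must be finite")
  if (theta < 0) stop("theta must be non-negative")
  (ic_curr - ic_prev) > theta
}

#' Segment a stream into statistically coherent chunks
#'
#' Applies the rise-in-surprisal boundary rule along the stream: a new chunk
#' starts wherever information content increases by more than `theta` bits
#' over the previous position, or when the running buffer reaches `max_len`.
#' The chunks partition the stream exactly.
#'
#' @param model a smoothed [TransitionModel-class] covering the stream's
#'   alphabet.
#' @param stream character vector or stream data.frame.
#' @param theta boundary threshold in bits.
#' @param max_len maximum chunk length before a forced boundary (default 16).
#' @return list of chunks; each chunk is a list with `members` (character),
#'   `span` (half-open `[start, end)` indices, so `span = c(i, j)` covers
#'   positions `i .. j-1`), `onset_ms` of its first member and `duration_ms`
#'   (time to the next chunk's onset, `NA` for the last chunk or untimed
#'   streams).
#' @export
chunkSequence <- function(model, stream, theta = 0, max_len = 16L) {
  if (max_len < 1L) stop("max_len must be at least 1")
  s <- .asStream(stream, viewpoint = model@viewpoint)
  n <- nrow(s)
  if (n == 0L) return(list())
  ic <- informationProfile(model, s, smooth = TRUE)
  starts <- 1L
  len <- 1L
  for (i in seq_len(n)[-1L]) {
    if (len >= max_len || boundaryDecision(ic[i - 1L], ic[i], theta)) {
      starts <- c(starts, i)
      len <- 1L
    } else {
      len <- len + 1L
    }
  }
  ends <- c(starts[-1L], n + 1L)
  onsets <- s$onset_ms
  lapply(seq_along(starts), function(j) {
    i0 <- starts[j]; i1 <- ends[j]
    dur <- if (j < length(starts) && !is.na(onsets[i0])) onsets[ends[j]] - onsets[i0] else NA_real_
    list(members = s$symbol[i0:(i1 - 1L)],
         span = c(i0, i1),
         onset_ms = onsets[i0],
         duration_ms = dur)
  })
}

#' Label chunks with next-level symbols
#'
#' Identical member sequences always receive the same label; new member
#' sequences extend the registry deterministically in first-encounter order.
#'
#' @param chunks list of chunks as returned by [chunkSequence()].
#' @param registry named list mapping existing labels to member vectors
#'   (empty by default).
#' @param level the level of the chunk members; labels are minted for level
#'   `level + 1` and look like `"L<level+1>_<n>"`.
#' @return list with `stream` (a data.frame of `symbol`/`onset_ms`, one row
#'   per chunk) and the extended `registry`.
#' @export
labelChunks <- function(chunks, registry = list(), level = 0L) {
  lookup <- if (length(registry))
    stats::setNames(names(registry), vapply(registry, .key, character(1)))
  else character(0)
  labels <- character(length(chunks))
  for (j in seq_along(chunks)) {
    key <- .key(chunks[[j]]$members)
    lab <- if (key %in% names(lookup)) lookup[[key]] else NULL
    if (is.null(lab)) {
      lab <- sprintf("L%d_%d", level + 1L, length(registry) + 1L)
      registry[[lab]] <- chunks[[j]]$members
      lookup[[key]] <- lab
    }
    labels[j] <- lab
  }
  onsets <- vapply(chunks, function(ch) {
    o <- ch$onset_ms
    if (is.null(o) || length(o) != 1L) NA_real_ else as.numeric(o)
  }, numeric(1))
  list(stream = data.frame(symbol = labels, onset_ms = onsets, stringsAsFactors = FALSE),
       registry = registry)
}

#' Build a layered chunk memory from a corpus
#'
#' Iterates train / chunk / label from the surface upward: at each level a
#' transition model is trained on the whole level (batch), every stream is
#' segmented by the rise-in-surprisal rule, and the chunks are labelled with
#' next-level symbols shared across streams. Building stops at `max_depth`,
#' when a level stops getting shorter, or when the next level's alphabet
#' would exceed `max_alphabet` (in which case that level is not built).
#'
#' @param corpus list of streams (character vectors or stream data.frames).
#' @param theta boundary threshold in bits (default 0).
#' @param max_depth maximum number of levels above the surface (>= 0).
#' @param max_alphabet cap on the alphabet size of any built level.
#' @param order,k transition-model order and smoothing constant per level.
#' @param max_len forced-flush buffer cap per chunk.
#' @param viewpoint feature-stream name recorded on the per-level models.
#' @return a [HierarchicalMemory-class].
#' @export
buildHierarchy <- function(corpus, theta = 0, max_depth = 3L, max_alphabet = Inf,
                           order = 1L, k = 1, max_len = 16L, viewpoint = "default") {
  max_depth <- as.integer(max_depth)
  if (max_depth < 0L) stop("max_depth must be >= 0")
  if (max_alphabet < 1) stop("max_alphabet must be >= 1")
  streams <- .asCorpus(corpus, viewpoint = viewpoint)
  if (sum(vapply(streams, nrow, integer(1))) == 0L) stop("corpus is empty")
  if (length(unique(unlist(lapply(streams, `[[`, "symbol")))) > max_alphabet)
    stop("surface alphabet already exceeds max_alphabet")

  levels <- list(streams)
  registries <- list()
  models <- list(trainTransitions(streams, order = order, k = k,
                                  viewpoint = viewpoint, level = 0L))

  d <- 0L
  while (d < max_depth) {
    cur <- levels[[d + 1L]]
    model <- models[[d + 1L]]
    chunked <- lapply(cur, chunkSequence, model = model, theta = theta, max_len = max_len)
    oldLen <- sum(vapply(cur, nrow, integer(1)))
    newLen <- sum(lengths(chunked))
    if (newLen >= oldLen) break  # no compression: every symbol is its own chunk
    types <- unique(unlist(lapply(chunked, function(cs)
      vapply(cs, function(ch) .key(ch$members), character(1)))))
    if (length(types) > max_alphabet) break
    registry <- list()
    nxt <- vector("list", length(chunked))
    for (i in seq_along(chunked)) {
      lab <- labelChunks(chunked[[i]], registry, level = d)
      registry <- lab$registry
      nxt[[i]] <- lab$stream
    }
    d <- d + 1L
    levels[[d + 1L]] <- nxt
    registries[[d]] <- registry
    models[[d + 1L]] <- trainTransitions(nxt, order = order, k = k,
                                         viewpoint = viewpoint, level = d)
  }

  new("HierarchicalMemory",
      levels = levels, registries = registries, models = models,
      theta = theta, maxLen = as.integer(max_len),
      maxDepth = max_depth, maxAlphabet = max_alphabet)
}

#' @describeIn buildHierarchy number of levels stored (surface included).
#' @param object a [HierarchicalMemory-class].
#' @export
setMethod("nLevels", "HierarchicalMemory", function(object) length(object@levels))

#' @describeIn buildHierarchy streams stored at one level (0 = surface).
#' @param level level index.
#' @export
setMethod("levelStreams", "HierarchicalMemory", function(object, level = 0L) {
  if (level < 0L || level >= length(object@levels)) stop("no such level")
  object@levels[[level + 1L]]
})

#' Per-level transition models of a memory
#' @param memory a [HierarchicalMemory-class].
#' @return list of [TransitionModel-class] objects, surface first.
#' @export
levelModels <- function(memory) memory@models

setMethod("show", "HierarchicalMemory", function(object) {
  sizes <- vapply(object@levels, function(lv) sum(vapply(lv, nrow, integer(1))), integer(1))
  alpha <- vapply(object@models, function(m) length(m@alphabet), integer(1))
  cat(sprintf("HierarchicalMemory: %d level(s), theta = %g bits\n", length(object@levels), object@theta))
  for (i in seq_along(sizes))
    cat(sprintf("  level %d: %d symbols over %d stream(s), alphabet %d\n",
                i - 1L, sizes[i], length(object@levels[[i]]), alpha[i]))
})

setMethod("reconstruct", "HierarchicalMemory", function(object, level = nLevels(object) - 1L) {
  if (level < 0L || level >= length(object@levels)) stop("no such level")
  out <- lapply(object@levels[[level + 1L]], `[[`, "symbol")
  if (level == 0L) return(out)
  for (d in level:1L) {
    reg <- object@registries[[d]]
    out <- lapply(out, function(syms) {
      if (!all(syms %in% names(reg)))
        stop("corrupted registry: label(s) missing at level ", d)
      unlist(reg[syms], use.names = FALSE)
    })
  }
  out
})
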