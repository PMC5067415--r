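#' @include AllClasses.R AllGenerics.R distributions.R utils.R
NULL

#' Train a Markov transition model on a corpus of symbol streams
#'
#' Counts exact n-gram transitions within each stream; streams are never
#' concatenated, so no transition crosses a stream boundary. Counts are kept
#' for every context length from 0 (symbol frequencies) up to `order`, which
#' is what prediction backs off through when a long context is unseen.
#'
#' @param corpus a stream or list of streams; a stream is a character vector
#'   of symbols or a data.frame with a `symbol` (or `viewpoint`-named) column
#'   and optionally `onset_ms`.
#' @param order maximum context length (default 1, a first-order model).
#' @param viewpoint name of the feature stream; with data.frame input it also
#'   selects the symbol column.
#' @param level hierarchy level of the symbols (0 = surface).
#' @param k additive smoothing constant used at prediction time (default 1);
#'   counts themselves are stored unsmoothed.
#' @param alphabet optional explicit alphabet; defaults to the symbols
#'   observed in the corpus. Declaring a larger alphabet gives unseen-but-
#'   possible symbols residual mass under smoothing.
#' @return a [TransitionModel-class].
#' @export
#' @examples
#' m <- trainTransitions(c("a", "b", "a", "b", "a", "c"))
#' predictNext(m, "a", smooth = FALSE)  # b: 2/3, c: 1/3
trainTransitions <- function(corpus, order = 1L, viewpoint = "default",
                             level = 0L, k = 1, alphabet = NULL) {
  order <- as.integer(order)
  if (order < 1L) stop("order must be a positive integer")
  streams <- .asCorpus(corpus, viewpoint = viewpoint)
  empty <- vapply(streams, function(s) nrow(s) == 0L, logical(1))
  if (any(empty)) {
    warning(sprintf("skipping %d empty stream(s)", sum(empty)))
    streams <- streams[!empty]
  }
  if (length(streams) == 0L) stop("corpus contains no non-empty streams")

  observed <- unique(unlist(lapply(streams, `[[`, "symbol"), use.names = FALSE))
  if (is.null(alphabet)) alphabet <- sort(observed)
  else if (!all(observed %in% alphabet))
    stop("corpus contains symbols outside the declared alphabet: ",
         paste(setdiff(observed, alphabet), collapse = ", "))

  counts <- vector("list", order + 1L)
  for (L in 0:order) {
    tab <- new.env(parent = emptyenv())
    for (s in streams) {
      syms <- s$symbol
      n <- length(syms)
      if (n < L + 1L) next
      from <- if (L == 0L) 1L else (L + 1L)
      for (i in from:n) {
        key <- if (L == 0L) .ctxKey(character(0)) else .key(syms[(i - L):(i - 1L)])
        nxt <- syms[i]
        cur <- tab[[key]]
        if (is.null(cur)) cur <- numeric(0)
        cur[nxt] <- if (is.na(cur[nxt])) 1 else cur[nxt] + 1
        tab[[key]] <- cur
      }
    }
    counts[[L + 1L]] <- as.list(tab)
  }

  new("TransitionModel",
      order = order, viewpoint = viewpoint, level = as.integer(level),
      alphabet = alphabet, counts = counts, smoothing = "add-k",
      k = k, nStreams = length(streams))
}

#' @describeIn trainTransitions alphabet accessor.
#' @param object a [TransitionModel-class].
#' @export
setMethod("alphabet", "TransitionModel", function(object) object@alphabet)

setMethod("show", "TransitionModel", function(object) {
  n1 <- length(object@counts[[min(2L, length(object@counts))]])
  cat(sprintf(
    "TransitionModel: order %d, viewpoint '%s', level %d\n  alphabet: %d symbols; %d order-1 contexts; %d stream(s); add-k smoothing (k = %g)\n",
    object@order, object@viewpoint, object@level,
    length(object@alphabet), n1, object@nStreams, object@k))
})

# Raw continuation counts for a context at its exact length (no back-off).
.contextCounts <- function(model, context) {
  L <- length(context)
  if (L > model@order) stop("context is longer than the model order")
  model@counts[[L + 1L]][[.ctxKey(context)]]
}

#' @describeIn predictNext smoothed continuation distribution with back-off.
#'
#' The distribution is the add-k smoothed relative frequency of the
#' continuations of `context` over the declared alphabet. A context that was
#' never observed (including contexts mentioning unknown symbols) backs off
#' to its suffix, and ultimately to the unigram distribution.
#'
#' @param smooth logical; if `FALSE`, k = 0 is used (maximum likelihood).
#' @export
setMethod("predictNext", "TransitionModel", function(object, context = character(0), ...,
                                                     smooth = TRUE) {
  if (length(object@counts) == 0L || length(object@counts[[1L]]) == 0L)
    stop("model has no training data")
  context <- as.character(context)
  if (length(context) > object@order)
    context <- context[(length(context) - object@order + 1L):length(context)]
  k <- if (smooth) object@k else 0
  L <- length(context)
  repeat {
    cts <- .contextCounts(object, if (L == 0L) character(0) else
      context[(length(context) - L + 1L):length(context)])
    if (!is.null(cts)) {
      full <- stats::setNames(rep(0, length(object@alphabet)), object@alphabet)
      full[names(cts)] <- cts
      tot <- sum(full) + k * length(full)
      if (tot > 0) {
        p <- (full + k) / tot
        if (any(p > 0)) return(assertDistribution(p))
      }
    }
    if (L == 0L) break
    L <- L - 1L
  }
  stop("model has no usable counts at any context length")
})

#' Per-position information content of a stream under a model
#'
#' For each position the surprisal of the observed symbol given its
#' preceding context (backed off as needed; the first position uses the
#' unigram distribution). This is the signal whose rises drive chunking and
#' whose peaks flag deviants.
#'
#' @param model a [TransitionModel-class].
#' @param stream a character vector or stream data.frame.
#' @param smooth logical, use add-k smoothing (default `TRUE`).
#' @return numeric vector of surprisal values in bits, one per position.
#' @export
informationProfile <- function(model, stream, smooth = TRUE) {
  s <- .asStream(stream, viewpoint = model@viewpoint)
  syms <- s$symbol
  n <- length(syms)
  out <- numeric(n)
  for (i in seq_len(n)) {
    ctx <- if (i == 1L) character(0) else syms[max(1L, i - model@order):(i - 1L)]
    d <- predictNext(model, ctx, smooth = smooth)
    if (!syms[i] %in% names(d) || d[[syms[i]]] == 0)
      stop(sprintf("symbol '%s' at position %d has zero mass; use a smoothed model whose alphabet covers the stream", syms[i], i))
    out[i] <- -log2(d[[syms[i]]])
  }
  out
}

#' Flag surprising positions in a stream
#'
#' Marks every position whose information content under the model exceeds
#' `threshold_bits` — an oddball detector: a deviant item embedded in a
#' repetitive sequence carries far more surprisal than its neighbours.
#'
#' @param model a smoothed [TransitionModel-class] whose alphabet covers the
#'   stream.
#' @param stream character vector or stream data.frame.
#' @param threshold_bits positive surprisal threshold in bits.
#' @return integer vector of flagged positions (possibly empty).
#' @export
#' @examples
#' m <- trainTransitions(rep("a", 50), alphabet = c("a", "b"), k = 1)
#' detectDeviants(m, c("a", "a", "a", "b", "a", "a"), threshold_bits = 3)
detectDeviants <- function(model, stream, threshold_bits) {
  if (!is.numeric(threshold_bits) || length(threshold_bits) != 1L || threshold_bits <= 0)
    stop("threshold_bits must be a single positive number")
  ic <- informationProfile(model, stream, smooth = TRUE)
  which(ic > threshold_bits)
}
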