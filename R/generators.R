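#' @include utils.R meter-space.R
NULL

# Built-in meter templates. Each position of the cycle carries a strength
# class symbol; classes double as the surface alphabet of generated events,
# the way percussion voices or melodic accents mark metrical position in
# real music: "db" downbeat, "mb" mid-bar, "bt" secondary beat, "ob"
# offbeat.
.meterTemplates <- list(
  "4/4" = list(
    structure = function(unit_ms) metricalStructure(list(2, 2, 2), unit_ms = unit_ms),
    positions = c("db", "ob", "bt", "ob", "mb", "ob", "bt", "ob")
  ),
  "7/8" = list(
    # the long-group start carries its own accent class (mb), as Balkan
    # practice accents it differently from the short-group start; this also
    # keeps the strong-beat skeleton phase-unambiguous for a first-order model
    structure = function(unit_ms) metricalStructure(list(c(2, 2, 3)), unit_ms = unit_ms),
    positions = c("db", "ob", "bt", "ob", "mb", "ob", "ob")
  ),
  "3/4" = list(
    structure = function(unit_ms) metricalStructure(list(3, 2), unit_ms = unit_ms),
    positions = c("db", "ob", "bt", "ob", "bt", "ob")
  ),
  "6/8" = list(
    structure = function(unit_ms) metricalStructure(list(2, 3), unit_ms = unit_ms),
    positions = c("db", "ob", "ob", "bt", "ob", "ob")
  )
)

#' Names of the built-in meter templates
#' @return character vector of template names.
#' @export
meterTemplates <- function() names(.meterTemplates)

#' The metrical structure of a built-in template
#' @param template template name, see [meterTemplates()].
#' @param unit_ms basic unit in ms.
#' @return a `MetricalStructure`.
#' @export
templateStructure <- function(template, unit_ms = 250) {
  tpl <- .meterTemplates[[template]]
  if (is.null(tpl)) stop("unknown meter template: ", template)
  tpl$structure(unit_ms)
}

#' Generate a corpus of metrical rhythm streams
#'
#' Onsets are placed on the metrical grid by independent Bernoulli draws
#' whose probability depends on the metrical strength of the position:
#' strong positions are articulated more often than weak ones, which is the
#' statistical asymmetry a listener learns meter from. Each event carries
#' its strength-class symbol (`db`/`mb`/`bt`/`ob`), standing in for the
#' accentual or timbral cues that mark metrical position in real music.
#'
#' @param template meter template name (default `"4/4"`).
#' @param probs named onset probabilities per strength class, strictly
#'   decreasing with decreasing metrical strength. Defaults
#'   `c(db = 1, mb = 0.85, bt = 0.65, ob = 0.2)`.
#' @param n_bars bars per stream (default 16).
#' @param n_streams streams in the corpus (default 20).
#' @param unit_ms duration of one grid pulse in ms (default 240, an eighth
#'   note at 125 bpm; a multiple of the 20 ms analysis quantum, so that
#'   grid positions coincide with analysis bins).
#' @param seed mandatory integer seed.
#' @return list of event data.frames (`symbol`, `onset_ms`), with the
#'   template name and parameters in attributes.
#' @export
genMeterCorpus <- function(template = "4/4",
                           probs = c(db = 1, mb = 0.85, bt = 0.65, ob = 0.2),
                           n_bars = 16L, n_streams = 20L, unit_ms = 240L,
                           seed) {
  if (missing(seed)) stop("seed is mandatory")
  if (n_bars < 1L) stop("n_bars must be >= 1")
  tpl <- .meterTemplates[[template]]
  if (is.null(tpl)) stop("unknown meter template: ", template)
  classes <- unique(tpl$positions)
  if (!all(classes %in% names(probs)))
    stop("probs must name every strength class used by the template: ",
         paste(classes, collapse = ", "))
  strengthOrder <- intersect(c("db", "mb", "bt", "ob"), classes)
  pOrdered <- probs[strengthOrder]
  if (any(probs < 0 | probs > 1)) stop("onset probabilities must lie in [0, 1]")
  # strictly decreasing with decreasing strength; classes may only tie at 0
  # (a degenerate pattern that omits the weaker classes altogether)
  strictOK <- all(diff(pOrdered) < 0 | (pOrdered[-1] == 0 & diff(pOrdered) <= 0))
  if (!strictOK || pOrdered[1] == 0)
    stop("onset probabilities must strictly decrease with decreasing metrical strength")

  set.seed(stageSeed(seed, "meter_corpus"))
  cyc <- length(tpl$positions)
  out <- vector("list", n_streams)
  for (s in seq_len(n_streams)) {
    pos <- rep(tpl$positions, n_bars)
    onset <- (seq_along(pos) - 1L) * unit_ms
    keep <- stats::runif(length(pos)) < probs[pos]
    keep[1L] <- TRUE  # streams are anchored at a downbeat
    out[[s]] <- data.frame(symbol = pos[keep], onset_ms = onset[keep],
                           stringsAsFactors = FALSE)
  }
  attr(out, "template") <- template
  attr(out, "unit_ms") <- unit_ms
  attr(out, "probs") <- probs
  out
}

#' Generate a word-segmentation stream with known boundaries
#'
#' Builds an artificial lexicon of `n_words` words of `word_len` symbols
#' each (all symbols distinct across words), concatenates `n_tokens`
#' uniform-random word tokens into one stream, and returns the true
#' word-start positions for scoring a segmenter. Within-word transitions are
#' deterministic; between-word transitions have probability `1/n_words`.
#'
#' @param n_words lexicon size (>= 2).
#' @param word_len symbols per word (>= 2).
#' @param n_tokens word tokens in the stream (default 300).
#' @param seed mandatory integer seed.
#' @return list with `stream` (character vector), `boundaries` (integer
#'   positions `> 1` where a new word starts) and `lexicon`.
#' @export
genSegmentationCorpus <- function(n_words = 4L, word_len = 3L, n_tokens = 300L, seed) {
  if (missing(seed)) stop("seed is mandatory")
  if (n_words < 2L) stop("lexicon size must be >= 2")
  if (word_len < 2L) stop("word length must be >= 2")
  lexicon <- lapply(seq_len(n_words), function(w)
    sprintf("p%02d", (w - 1L) * word_len + seq_len(word_len)))
  keys <- vapply(lexicon, paste, character(1), collapse = " ")
  if (anyDuplicated(keys)) warning("degenerate lexicon: duplicated words")
  set.seed(stageSeed(seed, "segmentation_corpus"))
  tokens <- sample.int(n_words, n_tokens, replace = TRUE)
  stream <- unlist(lexicon[tokens], use.names = FALSE)
  starts <- cumsum(c(1L, rep(word_len, n_tokens - 1L)))
  list(stream = stream, boundaries = starts[-1L], lexicon = lexicon)
}

#' Generate an ordered set of performance timing deviations
#'
#' Each performance is a vector of signed per-onset deviations (ms) from a
#' regularized rhythm. Three generating processes mirror the three timing
#' signatures: `"groove"` (constant offset on the backbeat positions plus
#' small jitter), `"inconsistent_error"` (zero-mean wide jitter), and
#' `"tempo_change"` (deviation magnitude growing linearly across
#' performances, an accelerando/rallentando trajectory).
#'
#' @param kind one of `"groove"`, `"inconsistent_error"`, `"tempo_change"`.
#' @param n_performances performances in the set (default 50).
#' @param n_onsets onsets per performance (default 8).
#' @param offset_ms groove displacement (default 15).
#' @param jitter_sd jitter s.d.: 3 for groove/tempo, 25 for inconsistent.
#' @param drift_ms_per_perf per-performance growth of the tempo-change
#'   deviation (default 2).
#' @param seed mandatory integer seed.
#' @return list of deviation vectors with the generating `kind` attribute.
#' @export
genPerformanceSet <- function(kind = c("groove", "inconsistent_error", "tempo_change"),
                              n_performances = 50L, n_onsets = 8L,
                              offset_ms = 15, jitter_sd = NULL,
                              drift_ms_per_perf = 2, seed) {
  if (missing(seed)) stop("seed is mandatory")
  kind <- match.arg(kind)
  if (is.null(jitter_sd)) jitter_sd <- if (kind == "inconsistent_error") 25 else 3
  set.seed(stageSeed(seed, paste0("performance_", kind)))
  backbeat <- seq_len(n_onsets) %in% c(3L, 7L)  # beats 2 and 4 of an 8-position bar
  out <- vector("list", n_performances)
  for (j in seq_len(n_performances)) {
    base <- switch(kind,
      groove = ifelse(backbeat, offset_ms, 0),
      inconsistent_error = rep(0, n_onsets),
      tempo_change = drift_ms_per_perf * j * (seq_len(n_onsets) / n_onsets))
    out[[j]] <- base + stats::rnorm(n_onsets, 0, jitter_sd)
  }
  attr(out, "kind") <- kind
  out
}

#' Score detected boundaries against true boundaries
#'
#' Precision/recall/F1 of exact boundary positions (position `i` means "a
#' chunk starts at `i`"); the trivial start of the stream is not scored.
#'
#' @param detected integer positions where detected chunks start (> 1).
#' @param truth integer positions where words truly start (> 1).
#' @return named numeric vector with `precision`, `recall`, `f1`.
#' @export
boundaryScore <- function(detected, truth) {
  detected <- setdiff(unique(detected), 1L)
  truth <- setdiff(unique(truth), 1L)
  tp <- length(intersect(detected, truth))
  precision <- if (length(detected)) tp / length(detected) else 0
  recall <- if (length(truth)) tp / length(truth) else 0
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  c(precision = precision, recall = recall, f1 = f1)
}

#' Chunk start positions of a chunk list
#' @param chunks list of chunks from [chunkSequence()].
#' @return integer vector of start indices.
#' @export
chunkStarts <- function(chunks) vapply(chunks, function(ch) ch$span[1L], numeric(1))

#' Generate noisy meter-space exemplars for a set of rhythm classes
#'
#' For each template, `n_each` performances are simulated by jittering the
#' boundary times of the metrical levels by `sigma_ms` and re-deriving the
#' level ratios / group proportions from the perturbed durations — so each
#' exemplar is the meter point a listener would estimate from one noisy
#' performance.
#'
#' @param templates character vector of template names.
#' @param n_each exemplars per template (default 40).
#' @param sigma_ms timing jitter s.d. in ms (default 10).
#' @param unit_ms basic unit (default 250).
#' @param include_tempo carry a tempo dimension (default `FALSE`).
#' @param seed mandatory integer seed.
#' @return list with `points` (list of [MeterPoint-class]) and `labels`.
#' @export
genMeterExemplars <- function(templates = c("4/4", "3/4", "6/8", "7/8"),
                              n_each = 40L, sigma_ms = 10, unit_ms = 250,
                              include_tempo = FALSE, seed) {
  if (missing(seed)) stop("seed is mandatory")
  set.seed(stageSeed(seed, "meter_exemplars"))
  # shared space: the union of the templates' dimensions; a template that
  # lacks a dimension sits at 0 there (its structure has no such level)
  ideal <- lapply(templates, function(tp)
    meterPoint(templateStructure(tp, unit_ms = unit_ms)))
  unionNames <- unique(unlist(lapply(ideal, function(p) names(p@coordinates))))
  unionDomains <- character(length(unionNames))
  names(unionDomains) <- unionNames
  for (p in ideal) unionDomains[names(p@coordinates)] <- p@domains
  if (include_tempo) {
    unionNames <- c(unionNames, "tempo")
    unionDomains <- c(unionDomains, tempo = "tempo")
  }

  points <- list()
  labels <- character(0)
  for (ti in seq_along(templates)) {
    tp <- templates[ti]
    ms <- templateStructure(tp, unit_ms = unit_ms)
    for (i in seq_len(n_each)) {
      coords <- stats::setNames(rep(0, length(unionNames)), unionNames)
      for (k in seq_along(ms$levels)) {
        lv <- ms$levels[[k]]
        if (length(lv) == 1L) {
          # ratio re-estimated from one noisy parent and one noisy child span
          parent <- lv * 2 * unit_ms + stats::rnorm(1, 0, sigma_ms)
          child <- 2 * unit_ms + stats::rnorm(1, 0, sigma_ms)
          coords[sprintf("L%d", k)] <- parent / child
        } else {
          parts <- pmax(1, lv * unit_ms + stats::rnorm(length(lv), 0, sigma_ms))
          coords[sprintf("L%d.g%d", k, seq_along(lv))] <- parts / sum(parts)
        }
      }
      if (include_tempo) coords["tempo"] <- unit_ms + stats::rnorm(1, 0, sigma_ms)
      points[[length(points) + 1L]] <- new("MeterPoint", coordinates = coords,
                                           domains = unname(unionDomains))
      labels <- c(labels, tp)
    }
  }
  list(points = points, labels = labels,
       dimensions = stats::setNames(unname(unionDomains), unionNames))
}
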