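#' @include chunking.R temporal.R
NULL

#' Write timed event streams as JSON Lines
#'
#' One header record (`type: "header"`) declaring the viewpoints and the
#' alphabet, then one record per event with its onset and per-viewpoint
#' symbol values, then a `type: "stream-break"` record between streams.
#'
#' @param corpus a stream or list of streams (`symbol` / `onset_ms`
#'   data.frames or character vectors).
#' @param path output file path.
#' @param viewpoint viewpoint name written in the records (default
#'   `"default"`).
#' @return `path`, invisibly.
#' @export
writeEventsJSONL <- function(corpus, path, viewpoint = "default") {
  streams <- .asCorpus(corpus)
  alphabet <- sort(unique(unlist(lapply(streams, `[[`, "symbol"))))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(jsonlite::toJSON(list(type = "header", viewpoints = list(viewpoint),
                                   alphabet = alphabet, n_streams = length(streams)),
                              auto_unbox = TRUE), con)
  for (si in seq_along(streams)) {
    s <- streams[[si]]
    for (i in seq_len(nrow(s))) {
      vals <- list()
      vals[[viewpoint]] <- s$symbol[i]
      rec <- list(viewpoint_values = vals,
                  onset_ms = if (is.na(s$onset_ms[i])) NULL else as.integer(s$onset_ms[i]))
      writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, null = "null"), con)
    }
    if (si < length(streams))
      writeLines(jsonlite::toJSON(list(type = "stream-break"), auto_unbox = TRUE), con)
  }
  invisible(path)
}

#' Read timed event streams from JSON Lines
#'
#' Inverse of [writeEventsJSONL()]. Malformed records are fatal and the
#' error names the offending line.
#'
#' @param path input file path.
#' @param viewpoint viewpoint to extract (default the first declared).
#' @return list of stream data.frames; the declared alphabet is attached as
#'   an attribute.
#' @export
readEventsJSONL <- function(path, viewpoint = NULL) {
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) == 0L) stop("empty JSONL file: ", path)
  parse1 <- function(i) {
    rec <- tryCatch(jsonlite::fromJSON(lines[i]),
                    error = function(e) stop(sprintf("%s: malformed JSON at line %d: %s",
                                                     path, i, conditionMessage(e)), call. = FALSE))
    rec
  }
  header <- parse1(1L)
  if (!identical(header$type, "header"))
    stop(sprintf("%s: line 1 must be a header record", path))
  if (is.null(viewpoint)) viewpoint <- header$viewpoints[[1L]]
  streams <- list()
  sym <- character(0); ons <- numeric(0)
  flush <- function() {
    if (length(sym))
      streams[[length(streams) + 1L]] <<- data.frame(symbol = sym, onset_ms = ons,
                                                     stringsAsFactors = FALSE)
    sym <<- character(0); ons <<- numeric(0)
  }
  for (i in seq_along(lines)[-1L]) {
    rec <- parse1(i)
    if (identical(rec$type, "stream-break")) { flush(); next }
    if (is.null(rec$viewpoint_values) || is.null(rec$viewpoint_values[[viewpoint]]))
      stop(sprintf("%s: line %d lacks a '%s' viewpoint value", path, i, viewpoint))
    sym <- c(sym, rec$viewpoint_values[[viewpoint]])
    ons <- c(ons, if (is.null(rec$onset_ms)) NA_real_ else as.numeric(rec$onset_ms))
  }
  flush()
  attr(streams, "alphabet") <- header$alphabet
  streams
}

#' Serialize a transition model to JSON
#' @param model a [TransitionModel-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeTransitionModel <- function(model, path) {
  counts <- lapply(model@counts, function(tab) lapply(tab, as.list))
  obj <- list(type = "transition_model", order = model@order,
              viewpoint = model@viewpoint, level = model@level,
              alphabet = model@alphabet, smoothing = model@smoothing,
              k = model@k, n_streams = model@nStreams, counts = counts)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a transition model from JSON
#' @param path input path.
#' @return a [TransitionModel-class].
#' @export
readTransitionModel <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(obj$type, "transition_model"))
    stop(path, " does not contain a transition model")
  counts <- lapply(obj$counts, function(tab)
    lapply(tab, function(cts) unlist(cts)))
  new("TransitionModel",
      order = as.integer(obj$order), viewpoint = obj$viewpoint,
      level = as.integer(obj$level),
      alphabet = unlist(obj$alphabet), counts = counts,
      smoothing = obj$smoothing, k = as.numeric(obj$k),
      nStreams = as.integer(obj$n_streams))
}

#' Serialize a hierarchical memory to JSON
#' @param memory a [HierarchicalMemory-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeMemory <- function(memory, path) {
  lv <- lapply(memory@levels, function(level) lapply(level, function(s)
    list(symbol = s$symbol, onset_ms = s$onset_ms)))
  obj <- list(type = "hierarchical_memory",
              theta = memory@theta, max_len = memory@maxLen,
              max_depth = memory@maxDepth,
              max_alphabet = if (is.finite(memory@maxAlphabet)) memory@maxAlphabet else "Inf",
              levels = lv,
              registries = memory@registries,
              model_params = list(order = memory@models[[1L]]@order,
                                  k = memory@models[[1L]]@k,
                                  viewpoint = memory@models[[1L]]@viewpoint))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Read a hierarchical memory from JSON
#'
#' Per-level transition models are retrained from the stored level streams,
#' which reproduces them exactly (training is deterministic).
#'
#' @param path input path.
#' @return a [HierarchicalMemory-class].
#' @export
readMemory <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(obj$type, "hierarchical_memory"))
    stop(path, " does not contain a hierarchical memory")
  levels <- lapply(obj$levels, function(level) lapply(level, function(s)
    data.frame(symbol = unlist(s$symbol),
               onset_ms = vapply(s$onset_ms, function(x)
                 if (is.null(x)) NA_real_ else as.numeric(x), numeric(1)),
               stringsAsFactors = FALSE)))
  registries <- lapply(obj$registries, function(reg) lapply(reg, unlist))
  mp <- obj$model_params
  models <- lapply(seq_along(levels), function(d)
    trainTransitions(levels[[d]], order = mp$order, k = mp$k,
                     viewpoint = mp$viewpoint, level = d - 1L))
  maxAlpha <- if (identical(obj$max_alphabet, "Inf")) Inf else as.numeric(obj$max_alphabet)
  new("HierarchicalMemory",
      levels = levels, registries = registries, models = models,
      theta = as.numeric(obj$theta), maxLen = as.integer(obj$max_len),
      maxDepth = as.integer(obj$max_depth), maxAlphabet = maxAlpha)
}

#' Write an expectation profile (or tap record) as CSV
#' @param x an [ExpectationProfile-class] or [TapRecord-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeTableCSV <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' Write meter points and labels as CSV
#' @param points list of [MeterPoint-class] in one space.
#' @param labels optional character labels.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writePointsCSV <- function(points, labels = NULL, path) {
  if (length(points) == 0L) stop("no points to write")
  nm <- names(points[[1L]]@coordinates)
  mat <- t(vapply(points, function(p) {
    if (!identical(names(p@coordinates), nm)) stop("points live in different spaces")
    p@coordinates
  }, numeric(length(nm))))
  df <- as.data.frame(mat)
  names(df) <- nm
  df$domain <- NULL
  if (!is.null(labels)) df$label <- labels
  attrLine <- paste(points[[1L]]@domains, collapse = ";")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# domains: ", attrLine), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read meter points (and labels) from CSV written by [writePointsCSV()]
#' @param path input path.
#' @return list with `points` and `labels` (`NULL` if absent).
#' @export
readPointsCSV <- function(path) {
  first <- readLines(path, n = 1L)
  if (!startsWith(first, "# domains: ")) stop(path, ": missing domain header line")
  domains <- strsplit(sub("^# domains: ", "", first), ";", fixed = TRUE)[[1L]]
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  labels <- if ("label" %in% names(df)) df$label else NULL
  coordCols <- setdiff(names(df), "label")
  points <- lapply(seq_len(nrow(df)), function(i)
    new("MeterPoint",
        coordinates = stats::setNames(as.numeric(df[i, coordCols]), coordCols),
        domains = domains))
  list(points = points, labels = labels)
}
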