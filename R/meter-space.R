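#' @include AllClasses.R AllGenerics.R
NULL

#' Define a metrical structure
#'
#' A metrical structure is the ordered list of subdivisions of one cycle,
#' from the whole cycle downward: `list(2, 2)` is a 4/4 bar split into
#' halves and then quarters; an additively grouped level is given as an
#' integer vector, so 7/8 with its 2+2+3 eighths is `list(c(2, 2, 3))`.
#'
#' @param levels list of subdivision ratios (single integers >= 2) and/or
#'   additive groups (integer vectors of length >= 2 with entries >= 1).
#' @param unit_ms optional basic unit (the duration of the lowest-level
#'   pulse) in milliseconds: the tempo of a concrete realization.
#' @return an object of class `MetricalStructure` (a validated list).
#' @export
metricalStructure <- function(levels, unit_ms = NULL) {
  if (!is.list(levels) || length(levels) == 0L) stop("levels must be a non-empty list")
  for (lv in levels) {
    if (!is.numeric(lv) || any(lv != round(lv))) stop("levels must be integer-valued")
    if (length(lv) == 1L) {
      if (lv < 2) stop("a subdivision ratio must be >= 2")
    } else {
      if (any(lv < 1)) stop("additive group lengths must be >= 1")
    }
  }
  if (!is.null(unit_ms) && (!is.numeric(unit_ms) || unit_ms <= 0))
    stop("unit_ms must be a positive duration")
  structure(list(levels = levels, unit_ms = unit_ms), class = "MetricalStructure")
}

#' Number of basic pulses in one cycle of a metrical structure
#' @param ms a `MetricalStructure`.
#' @return integer pulse count (e.g. 8 for 4/4 in eighths, 7 for 2+2+3).
#' @export
cycleLength <- function(ms) {
  stopifnot(inherits(ms, "MetricalStructure"))
  n <- 1
  for (lv in ms$levels) n <- n * if (length(lv) == 1L) lv else sum(lv)
  as.integer(n)
}

#' Embed a metrical structure as a point in meter space
#'
#' Coordinates are the subdivision ratios, one quality dimension per level;
#' an additive group contributes its normalized group-length vector (one
#' dimension per group, summing to 1) on that level's domain. With
#' `include_tempo = TRUE` the basic unit in ms is added as a separate tempo
#' domain; omitting it abstracts the meter from tempo.
#'
#' @param ms a `MetricalStructure`.
#' @param include_tempo include the tempo dimension (requires `unit_ms`).
#' @return a [MeterPoint-class].
#' @export
#' @examples
#' meterPoint(metricalStructure(list(2, 2), unit_ms = 250), include_tempo = TRUE)
#' meterPoint(metricalStructure(list(c(2, 2, 3))))
meterPoint <- function(ms, include_tempo = FALSE) {
  stopifnot(inherits(ms, "MetricalStructure"))
  coords <- numeric(0)
  domains <- character(0)
  for (i in seq_along(ms$levels)) {
    lv <- ms$levels[[i]]
    dom <- sprintf("L%d", i)
    if (length(lv) == 1L) {
      coords[sprintf("L%d", i)] <- lv
      domains <- c(domains, dom)
    } else {
      g <- lv / sum(lv)
      nm <- sprintf("L%d.g%d", i, seq_along(lv))
      coords[nm] <- g
      domains <- c(domains, rep(dom, length(lv)))
    }
  }
  if (include_tempo) {
    if (is.null(ms$unit_ms)) stop("include_tempo requires a structure with unit_ms")
    coords["tempo"] <- ms$unit_ms
    domains <- c(domains, "tempo")
  }
  new("MeterPoint", coordinates = coords, domains = domains)
}

setMethod("coordinates", "MeterPoint", function(object) object@coordinates)

setMethod("abstractTempo", "MeterPoint", function(object) {
  keep <- object@domains != "tempo"
  new("MeterPoint", coordinates = object@coordinates[keep],
      domains = object@domains[keep])
})

setMethod("show", "MeterPoint", function(object) {
  cat("MeterPoint:", paste(sprintf("%s=%.4g", names(object@coordinates),
                                   object@coordinates), collapse = ", "), "\n")
})

.sameSpace <- function(p, q) {
  identical(names(p@coordinates), names(q@coordinates)) &&
    identical(p@domains, q@domains)
}

#' Distance between two meter points
#'
#' Euclidean within each domain (a domain's dimensions are integral: they
#' are judged together), city-block across domains (domains are separable:
#' their contributions add). Points must live in the same space.
#'
#' @param p,q [MeterPoint-class] objects with identical dimensions.
#' @param scale optional named numeric vector of per-dimension scale factors
#'   (divisors) applied before measuring, modelling salience shifts; `NULL`
#'   (default) applies none.
#' @return non-negative distance.
#' @export
meterDistance <- function(p, q, scale = NULL) {
  if (!is(p, "MeterPoint") || !is(q, "MeterPoint")) stop("p and q must be MeterPoint objects")
  if (!.sameSpace(p, q)) stop("points live in different meter spaces")
  dp <- p@coordinates
  dq <- q@coordinates
  if (!is.null(scale)) {
    if (!all(names(dp) %in% names(scale))) stop("scale must name every dimension")
    dp <- dp / scale[names(dp)]
    dq <- dq / scale[names(dq)]
  }
  diffs <- dp - dq
  perDomain <- tapply(diffs, p@domains, function(v) sqrt(sum(v^2)))
  sum(perDomain)
}

#' Nearest-neighbour classification in meter space
#'
#' Assigns the query the label of its nearest training point under
#' [meterDistance()]. Distance ties are broken deterministically in favour
#' of the label earliest in sorted label order, then the earliest point.
#'
#' @param points list of [MeterPoint-class] training points.
#' @param labels character vector of training labels, one per point.
#' @param query a [MeterPoint-class].
#' @param scale optional per-dimension scaling, as in [meterDistance()].
#' @return the predicted label (character).
#' @export
classifyNN <- function(points, labels, query, scale = NULL) {
  if (length(points) == 0L) stop("training set is empty")
  if (length(points) != length(labels)) stop("one label per training point is required")
  d <- vapply(points, meterDistance, numeric(1), q = query, scale = scale)
  best <- which(d <= min(d) + 1e-12)
  if (length(best) > 1L) {
    ranks <- match(labels[best], sort(unique(labels)))
    best <- best[order(ranks, best)][1L]
  }
  labels[[best]]
}

#' Diagnose the statistical character of performance timing
#'
#' Given an ordered sequence of performances of the same regularized rhythm
#' (each a vector of signed per-onset deviations in ms), distinguishes three
#' signatures: a *groove* is a tight cluster displaced from the regularized
#' rhythm (large consistent offset, small dispersion); *inconsistent errors*
#' form a wide cloud around it (large dispersion, no trend); a *tempo
#' change* is a monotone trajectory (deviation magnitude growing or
#' shrinking with performance index). Tempo change is tested first (a drift
#' also inflates dispersion), then groove; anything else is treated as
#' inconsistent error.
#'
#' @param performances list (>= 5) of equal-length numeric deviation
#'   vectors, ordered in time, or a numeric matrix with one row per
#'   performance.
#' @param offset_min smallest per-position mean offset magnitude (ms) that
#'   counts as a groove displacement (default 8).
#' @param disp_max largest pooled within-position standard deviation (ms)
#'   compatible with a groove (default 15).
#' @param trend_min smallest Spearman correlation of per-performance
#'   deviation magnitude against index that counts as a tempo change
#'   (default 0.8).
#' @return a [TimingDiagnosis-class].
#' @export
diagnoseTiming <- function(performances, offset_min = 8, disp_max = 15, trend_min = 0.8) {
  mat <- if (is.matrix(performances)) performances else {
    if (length(performances) < 5L) stop("at least 5 performances are required")
    do.call(rbind, performances)
  }
  if (nrow(mat) < 5L) stop("at least 5 performances are required")
  if (any(!is.finite(mat))) stop("deviations must be finite")

  posMeans <- colMeans(mat)
  offset <- max(abs(posMeans))
  dispersion <- sqrt(mean(sweep(mat, 2L, posMeans)^2))
  magnitudes <- rowMeans(abs(mat))
  trend <- suppressWarnings(
    stats::cor(magnitudes, seq_len(nrow(mat)), method = "spearman"))
  if (!is.finite(trend)) trend <- 0

  label <- if (trend >= trend_min) "tempo_change"
  else if (offset > offset_min && dispersion < disp_max) "groove"
  else "inconsistent_error"

  new("TimingDiagnosis", label = label, offsetMs = offset,
      dispersionMs = dispersion, trend = trend)
}

#' Label of a timing diagnosis
#' @param x a [TimingDiagnosis-class].
#' @return character label.
#' @export
diagnosisLabel <- function(x) x@label

setMethod("show", "TimingDiagnosis", function(object) {
  cat(sprintf(
    "TimingDiagnosis: %s\n  max |position mean| %.2f ms; dispersion %.2f ms; trend rho %.2f\n",
    object@label, object@offsetMs, object@dispersionMs, object@trend))
})
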