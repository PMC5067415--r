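test_that("degenerate timing puts all mass at the observed interval's bin", {
  ev <- isoStream(20, 500)
  m <- trainTransitions(ev)
  tm <- observeTiming(m, ev, quantum_ms = 20, horizon_ms = 2000)
  d <- temporalDistribution(tm, "x", "x", smooth = FALSE)
  expect_equal(gridTimes(tm)[which.max(d)], 500)
  expect_equal(max(d), 1)
  expect_equal(sum(d), 1, tolerance = 1e-9)
})

test_that("a two-valued interval census yields two equal modes", {
  set.seed(12)
  iois <- sample(rep(c(400, 600), 50))
  ev <- data.frame(symbol = rep("x", 101), onset_ms = c(0, cumsum(iois)))
  m <- trainTransitions(ev)
  tm <- observeTiming(m, ev, horizon_ms = 2000)
  d <- temporalDistribution(tm, "x", "x", smooth = FALSE)
  expect_equal(unname(d[.binHit(tm, 400)]), 0.5)
  expect_equal(unname(d[.binHit(tm, 600)]), 0.5)
})

test_that("mirrored interval sets give symmetric densities", {
  base <- c(300, 340, 380, 420, 460, 500)
  iois <- c(base, 800 - base)  # symmetric about 400
  ev <- data.frame(symbol = rep("x", length(iois) + 1), onset_ms = c(0, cumsum(iois)))
  m <- trainTransitions(ev)
  tm <- observeTiming(m, ev, quantum_ms = 20, horizon_ms = 820)
  d <- temporalDistribution(tm, "x", "x", smooth = FALSE)
  ctr <- .binHit(tm, 400)
  span <- min(ctr - 1, length(d) - ctr)
  expect_equal(d[ctr + seq_len(span)], d[ctr - seq_len(span)])
})

test_that("unseen transitions are uniform with smoothing and an error without", {
  ev <- isoStream(10, 500)
  m <- trainTransitions(ev, alphabet = c("x", "y"))
  tm <- observeTiming(m, ev, horizon_ms = 1000)
  d <- temporalDistribution(tm, "x", "y")  # never observed
  expect_equal(d, rep(1 / 50, 50))
  expect_error(temporalDistribution(tm, "x", "y", smooth = FALSE), "smoothing")
  # smoothed distribution entropy is the full log2(bins) for the unseen pair
  expect_equal(-sum(d * log2(d)), log2(50))
})

test_that("negative intervals and untimed events are rejected", {
  bad <- data.frame(symbol = c("a", "b"), onset_ms = c(100, 50))
  m <- trainTransitions(c("a", "b"))
  expect_error(.asStream(bad), "non-decreasing")
  noTime <- data.frame(symbol = c("a", "b"), onset_ms = c(NA, NA))
  expect_error(observeTiming(m, noTime), "time-stamped")
})

test_that("disjoint temporal supports make the instantaneous distribution decisive", {
  # two continuations, equal sequence probability, non-overlapping timing
  ev <- data.frame(symbol = rep(c("c", "a", "c", "b"), 20),
                   onset_ms = cumsum(rep(c(1000, 300, 700, 600), 20)) - 1000)
  m <- trainTransitions(ev, k = 0.01)
  tm <- observeTiming(m, ev, horizon_ms = 2000)
  dA <- instantaneousDistribution(tm, m, "c", 300, smooth = FALSE)
  expect_equal(unname(dA["a"]), 1)
  dB <- instantaneousDistribution(tm, m, "c", 600, smooth = FALSE)
  expect_equal(unname(dB["b"]), 1)
  expect_error(instantaneousDistribution(tm, m, "c", -5), "non-negative")
})

test_that("instantaneous distributions match the product-and-renormalize oracle", {
  # three symbols with hand-set preferred times, probed at three instants
  set.seed(3)
  mk <- function(sym, mu, n = 40) {
    starts <- seq(0, by = 2000, length.out = n)
    data.frame(symbol = as.vector(rbind("c", sym)),
               onset_ms = as.vector(rbind(starts, starts + round(stats::rnorm(n, mu, 40)))))
  }
  ev <- list(mk("alpha", 300), mk("beta", 600), mk("gamma", 900))
  m <- trainTransitions(ev, k = 1)
  tm <- observeTiming(m, ev, horizon_ms = 2000)
  pWhat <- predictNext(m, "c")
  for (t in c(300, 600, 900)) {
    w <- vapply(names(pWhat), function(s)
      pWhat[[s]] * temporalDistribution(tm, "c", s)[.binHit(tm, t)], numeric(1))
    oracle <- w / sum(w)
    expect_equal(instantaneousDistribution(tm, m, "c", t), oracle, tolerance = 1e-12)
  }
})

test_that("continuation timing disambiguates a lexical garden path incrementally", {
  # two continuations of /ba NG .../: a word-final stop arriving early, or
  # the same stop opening the next word and arriving late. The posterior at
  # a probe before the late onset favours the early continuation and vice
  # versa, purely on timing.
  set.seed(8)
  mkWord <- function(stop_sym, mu, n = 30) {
    starts <- seq(0, by = 1500, length.out = n)
    data.frame(symbol = as.vector(rbind("ng", stop_sym)),
               onset_ms = as.vector(rbind(starts, starts + round(stats::rnorm(n, mu, 15)))))
  }
  corpus <- list(mkWord("k_final", 80), mkWord("k_onset", 220))
  m <- trainTransitions(corpus, k = 1)
  # the long silences between word tokens fall beyond the horizon by design
  tm <- suppressWarnings(observeTiming(m, corpus, horizon_ms = 600))
  early <- instantaneousDistribution(tm, m, "ng", 80)
  late <- instantaneousDistribution(tm, m, "ng", 220)
  expect_gt(early[["k_final"]], 0.9)
  expect_gt(late[["k_onset"]], 0.9)
})

test_that("learned densities recover a known renewal generator", {
  # two-state chain with per-transition interval atoms, n = 500 events
  set.seed(500)
  n <- 500
  sym <- character(n); ioi <- numeric(n)
  sym[1] <- "a"
  for (i in 2:n) {
    if (sym[i - 1] == "a") { sym[i] <- "b"; ioi[i] <- sample(c(400, 600), 1, prob = c(0.6, 0.4)) }
    else { sym[i] <- "a"; ioi[i] <- sample(c(240, 480), 1, prob = c(0.3, 0.7)) }
  }
  ev <- data.frame(symbol = sym, onset_ms = cumsum(c(0, ioi[-1])))
  m <- trainTransitions(ev)
  tm <- observeTiming(m, ev, horizon_ms = 1000)
  nb <- length(tm@marginal)

  genAB <- numeric(nb); genAB[.binHit(tm, 400)] <- 0.6; genAB[.binHit(tm, 600)] <- 0.4
  genBA <- numeric(nb); genBA[.binHit(tm, 240)] <- 0.3; genBA[.binHit(tm, 480)] <- 0.7
  for (pair in list(list("a", "b", genAB), list("b", "a", genBA))) {
    d <- temporalDistribution(tm, pair[[1]], pair[[2]], smooth = FALSE)
    tv <- 0.5 * sum(abs(d - pair[[3]]))
    expect_lte(tv, 0.1)
    modeGap <- abs(gridTimes(tm)[which.max(d)] - gridTimes(tm)[which.max(pair[[3]])])
    expect_lte(modeGap, tm@quantumMs)
  }
})

test_that("every stored density normalizes within tolerance", {
  corp <- genMeterCorpus(seed = 4, n_streams = 3, n_bars = 8)
  m <- trainTransitions(corp)
  tm <- suppressWarnings(observeTiming(m, corp))
  for (key in names(tm@table)[1:min(10, length(tm@table))]) {
    cts <- tm@table[[key]]
    expect_equal(sum(cts / sum(cts)), 1, tolerance = 1e-9)
  }
})
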