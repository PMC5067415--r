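test_that("metrical corpora honour their onset probabilities", {
  # degenerate: downbeats only, isochronous at the bar period
  corp <- genMeterCorpus(probs = c(db = 1, mb = 0, bt = 0, ob = 0),
                         n_bars = 8, n_streams = 2, seed = 1)
  for (s in corp) {
    expect_true(all(s$symbol == "db"))
    expect_equal(unique(diff(s$onset_ms)), 8 * 240)
  }

  # census over 1000 bars: empirical frequency within 2 points of spec
  probs <- c(db = 1, mb = 0.85, bt = 0.65, ob = 0.2)
  big <- genMeterCorpus(probs = probs, n_bars = 100, n_streams = 10, seed = 33)
  pos <- unlist(lapply(big, function(s) (s$onset_ms / 240) %% 8))
  classOf <- c("db", "ob", "bt", "ob", "mb", "ob", "bt", "ob")
  nBars <- 100 * 10
  counts <- table(factor(classOf[pos + 1], levels = names(probs)))
  perPos <- c(db = 1, mb = 1, bt = 2, ob = 4) * nBars
  emp <- as.numeric(counts) / perPos[names(probs)]
  expect_true(all(abs(emp - probs) <= 0.02))

  expect_error(genMeterCorpus(probs = c(db = 0.5, mb = 0.85, bt = 0.65, ob = 0.2),
                              seed = 1), "strictly decrease")
  expect_error(genMeterCorpus(n_bars = 0, seed = 1), "n_bars")
})

test_that("segmentation streams have the designed transition structure", {
  gen <- genSegmentationCorpus(n_words = 4, word_len = 3, n_tokens = 300, seed = 8)
  expect_length(gen$stream, 900)
  expect_length(gen$boundaries, 299)
  m <- trainTransitions(gen$stream, k = 0.001)
  # within-word transitions are deterministic
  w <- gen$lexicon[[1]]
  expect_gt(predictNext(m, w[1], smooth = FALSE)[[w[2]]], 0.999)
  # between-word transitions are close to uniform over the 4 word onsets
  lastSym <- gen$lexicon[[2]][3]
  onsetSyms <- vapply(gen$lexicon, `[`, character(1), 1)
  d <- predictNext(m, lastSym, smooth = FALSE)
  expect_true(all(abs(d[onsetSyms] - 0.25) < 0.12))

  # split-half stationarity of transition counts
  half <- length(gen$stream) %/% 2
  m1 <- trainTransitions(gen$stream[1:half])
  m2 <- trainTransitions(gen$stream[(half + 1):length(gen$stream)])
  c1 <- modelCounts(m1, lastSym); c2 <- modelCounts(m2, lastSym)
  keys <- union(names(c1), names(c2))
  tab <- rbind(sapply(keys, function(k) if (k %in% names(c1)) c1[[k]] else 0),
               sapply(keys, function(k) if (k %in% names(c2)) c2[[k]] else 0))
  p <- suppressWarnings(stats::chisq.test(tab)$p.value)
  expect_gt(p, 0.01)

  expect_error(genSegmentationCorpus(n_words = 1, seed = 1), ">= 2")
})

test_that("performance sets carry the statistics their kind declares", {
  g <- genPerformanceSet("groove", seed = 21)
  mat <- do.call(rbind, g)
  backMean <- mean(mat[, c(3, 7)])
  expect_lt(abs(backMean - 15), 2)
  e <- genPerformanceSet("inconsistent_error", seed = 21)
  sdE <- stats::sd(unlist(e))
  expect_lt(abs(sdE - 25) / 25, 0.2)
  t <- genPerformanceSet("tempo_change", seed = 21)
  mags <- vapply(t, function(x) mean(abs(x)), numeric(1))
  expect_gt(stats::coef(stats::lm(mags ~ seq_along(mags)))[2], 0)
})

test_that("generation is deterministic per seed and differs across seeds", {
  a <- genMeterCorpus(seed = 5); b <- genMeterCorpus(seed = 5)
  expect_identical(a, b)
  c <- genMeterCorpus(seed = 6)
  expect_false(identical(a, c))
  expect_error(genMeterCorpus(), "seed")
  s1 <- genSegmentationCorpus(seed = 5); s2 <- genSegmentationCorpus(seed = 5)
  expect_identical(s1, s2)
})

test_that("event streams round-trip through JSONL byte-identically", {
  corp <- genMeterCorpus(seed = 1, n_streams = 3, n_bars = 4)
  f1 <- tempfile(fileext = ".jsonl"); f2 <- tempfile(fileext = ".jsonl")
  writeEventsJSONL(corp, f1)
  rt <- readEventsJSONL(f1)
  writeEventsJSONL(rt, f2)
  expect_identical(readLines(f1), readLines(f2))
  for (i in seq_along(corp)) {
    expect_identical(rt[[i]]$symbol, corp[[i]]$symbol)
    expect_equal(rt[[i]]$onset_ms, as.numeric(corp[[i]]$onset_ms))
  }
})

test_that("malformed JSONL is reported with its line number", {
  f <- tempfile(fileext = ".jsonl")
  corp <- genMeterCorpus(seed = 1, n_streams = 1, n_bars = 2)
  writeEventsJSONL(corp, f)
  lines <- readLines(f)
  writeLines(c(lines[1:3], substr(lines[4], 1, 10)), f)  # truncate line 4
  expect_error(readEventsJSONL(f), "line 4")
})

test_that("models and memories round-trip through JSON", {
  gen <- genSegmentationCorpus(seed = 44, n_tokens = 60)
  m <- trainTransitions(gen$stream, k = 0.5)
  f <- tempfile(fileext = ".json")
  writeTransitionModel(m, f)
  m2 <- readTransitionModel(f)
  expect_equal(predictNext(m, gen$stream[5]), predictNext(m2, gen$stream[5]))
  expect_identical(alphabet(m), alphabet(m2))

  corp <- genMeterCorpus(seed = 2, n_streams = 2, n_bars = 4)
  mem <- suppressWarnings(buildHierarchy(corp, max_depth = 2))
  fm <- tempfile(fileext = ".json")
  writeMemory(mem, fm)
  mem2 <- readMemory(fm)
  expect_identical(reconstruct(mem), reconstruct(mem2))
  expect_equal(levelStreams(mem, 0), levelStreams(mem2, 0))
})

test_that("meter points round-trip through CSV with labels and domains", {
  ex <- genMeterExemplars(n_each = 3, seed = 12)
  f <- tempfile(fileext = ".csv")
  writePointsCSV(ex$points, ex$labels, f)
  rt <- readPointsCSV(f)
  expect_equal(rt$labels, ex$labels)
  for (i in seq_along(ex$points))
    expect_equal(coordinates(rt$points[[i]]), coordinates(ex$points[[i]]),
                 tolerance = 1e-12)
  expect_equal(meterDistance(rt$points[[1]], rt$points[[5]]),
               meterDistance(ex$points[[1]], ex$points[[5]]), tolerance = 1e-12)
})

test_that("CLI stages compose through files", {
  dir <- tempfile(); dir.create(dir)
  ev <- file.path(dir, "corpus.jsonl")
  suppressMessages(rhythmicsCLI(c("simulate", "--kind", "meter", "--seed", "9",
                                  "--bars", "4", "--streams", "3", "-o", ev)))
  expect_true(file.exists(ev))
  mod <- file.path(dir, "model.json")
  suppressMessages(rhythmicsCLI(c("train", "--order", "1", "--k", "1", ev, "-o", mod)))
  expect_s4_class(readTransitionModel(mod), "TransitionModel")
  memf <- file.path(dir, "memory.json")
  suppressMessages(rhythmicsCLI(c("chunk", "--theta", "0", "--max-depth", "2",
                                  ev, "-o", memf)))
  prof <- file.path(dir, "profile.csv")
  suppressMessages(suppressWarnings(
    rhythmicsCLI(c("profile", "--horizon", "3840", memf, "-o", prof))))
  df <- utils::read.csv(prof)
  expect_true(all(c("bin_start_ms", "strength") %in% names(df)))
  expect_error(capture.output(suppressMessages(rhythmicsCLI("nonsense"))),
               "unknown command")
})
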