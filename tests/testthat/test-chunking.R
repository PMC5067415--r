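test_that("boundary decisions follow the rise-in-surprisal rule", {
  expect_false(boundaryDecision(1.0, 1.0, 0))
  expect_true(boundaryDecision(0.2, 3.0, 0))
  expect_false(boundaryDecision(0.2, 3.0, 5.0))
  expect_error(boundaryDecision(Inf, 1, 0), "finite")
  expect_error(boundaryDecision(1, 1, -1), "non-negative")
})

test_that("a flat repetitive stream forms a single chunk (below the buffer cap)", {
  m <- trainTransitions(rep("a", 40))
  ch <- chunkSequence(m, rep("a", 5))
  expect_length(ch, 1)
  expect_equal(ch[[1]]$members, rep("a", 5))
  expect_equal(chunkSequence(m, character(0)), list())
})

test_that("chunks always partition the stream exactly", {
  set.seed(31)
  for (rep in 1:15) {
    stream <- sample(letters[1:4], sample(5:120, 1), replace = TRUE)
    m <- trainTransitions(stream)
    ch <- chunkSequence(m, stream, theta = stats::runif(1, 0, 2),
                        max_len = sample(3:20, 1))
    expect_equal(unlist(lapply(ch, `[[`, "members")), stream)
    spans <- vapply(ch, `[[`, numeric(2), "span")
    expect_equal(spans[1, 1], 1)
    expect_equal(spans[2, ncol(spans)], length(stream) + 1)
    if (ncol(spans) > 1)
      expect_equal(spans[1, -1], spans[2, -ncol(spans)])  # half-open, contiguous
  }
})

test_that("boundaries on a concatenated-word stream fall at the word joins", {
  # words have deterministic insides and uncertain joins, so surprisal
  # rises exactly at word onsets
  gen <- genSegmentationCorpus(n_words = 4, word_len = 3, n_tokens = 300, seed = 2024)
  m <- trainTransitions(gen$stream, k = 1)
  ch <- chunkSequence(m, gen$stream)
  sc <- boundaryScore(chunkStarts(ch), gen$boundaries)
  expect_gte(sc["f1"], 0.9)

  # the surprisal sequence itself shows the signature: low within words,
  # about log2(lexicon size) at joins
  ic <- informationProfile(m, gen$stream)
  joins <- gen$boundaries
  within <- setdiff(seq_along(gen$stream)[-1], joins)
  expect_gt(min(ic[joins]), max(ic[within]))
})

test_that("raising theta never increases the number of boundaries", {
  gen <- genSegmentationCorpus(seed = 5)
  m <- trainTransitions(gen$stream, k = 1)
  nb <- vapply(c(0, 0.5, 1, 2, 4), function(th)
    length(chunkSequence(m, gen$stream, theta = th, max_len = 10000L)), numeric(1))
  expect_true(all(diff(nb) <= 0))
})

test_that("identical member sequences share labels; labelling is isomorphic across runs", {
  m <- trainTransitions(c("a", "b", "a", "b"))
  chunks <- list(list(members = c("a", "b"), span = c(1, 3), onset_ms = 0, duration_ms = NA),
                 list(members = c("a", "b"), span = c(3, 5), onset_ms = 100, duration_ms = NA),
                 list(members = c("b"), span = c(5, 6), onset_ms = 200, duration_ms = NA))
  lab <- labelChunks(chunks, level = 0L)
  expect_equal(lab$stream$symbol[1], lab$stream$symbol[2])
  expect_false(lab$stream$symbol[1] == lab$stream$symbol[3])
  expect_length(lab$registry, 2)

  # fresh registries give an isomorphic labelling: same co-occurrence pattern
  lab2 <- labelChunks(rev(chunks), level = 0L)
  mapping <- unique(cbind(lab$stream$symbol, rev(lab2$stream$symbol)))
  expect_equal(nrow(mapping), length(unique(lab$stream$symbol)))
})

test_that("a zero-depth memory holds only the surface and its model", {
  gen <- genSegmentationCorpus(seed = 9)
  mem <- buildHierarchy(list(gen$stream), max_depth = 0)
  expect_equal(nLevels(mem), 1)
  expect_length(levelModels(mem), 1)
})

test_that("a four-word corpus yields a four-symbol level-1 alphabet", {
  gen <- genSegmentationCorpus(n_words = 4, word_len = 3, n_tokens = 300, seed = 77)
  mem <- buildHierarchy(list(gen$stream), max_depth = 1)
  expect_equal(nLevels(mem), 2)
  lvl1 <- levelStreams(mem, 1)[[1]]
  expect_equal(length(unique(lvl1$symbol)), 4)
  # brute-force chunk census agrees: the words are the only repeated types
  expect_setequal(vapply(mem@registries[[1]], paste, character(1), collapse = " "),
                  vapply(gen$lexicon, paste, character(1), collapse = " "))
})

test_that("phrases need a deeper hierarchy than words to become memorable", {
  # a 4-word lexicon heard in every two-word combination: surprisal rises at
  # the word joins, so one chunking layer makes the words memorable (each
  # gets a label) but a two-word phrase spans two labels and has no single
  # symbol; a second layer gives each phrase one
  lex <- list(c("w", "o", "k"), c("i", "e", "s"), c("b", "a", "l"), c("f", "u", "d"))
  corpus <- list()
  for (i in 1:4) for (j in 1:4) for (rep in 1:3)
    corpus[[length(corpus) + 1L]] <- c(lex[[i]], lex[[j]])

  mem1 <- buildHierarchy(corpus, max_depth = 1)
  expect_equal(nLevels(mem1), 2)
  lvl1 <- levelStreams(mem1, 1)
  expect_true(all(vapply(lvl1, nrow, integer(1)) == 2))  # two word labels per phrase
  expect_setequal(vapply(mem1@registries[[1]], paste, character(1), collapse = ""),
                  vapply(lex, paste, character(1), collapse = ""))

  mem2 <- buildHierarchy(corpus, max_depth = 2)
  expect_equal(nLevels(mem2), 3)
  lvl2 <- levelStreams(mem2, 2)
  expect_true(all(vapply(lvl2, nrow, integer(1)) == 1))  # one phrase label
  expect_equal(unlist(mem2@registries[[1]][mem2@registries[[2]][[lvl2[[1]]$symbol[1]]]],
                      use.names = FALSE),
               corpus[[1]])
})

test_that("reconstruction reproduces the surface exactly on randomized corpora", {
  for (seed in 1:20) {
    gen <- genSegmentationCorpus(n_words = sample(2:6, 1), word_len = sample(2:4, 1),
                                 n_tokens = 120, seed = seed)
    mem <- buildHierarchy(list(gen$stream), max_depth = 3)
    for (lev in seq_len(nLevels(mem)) - 1L)
      expect_identical(reconstruct(mem, lev)[[1]], gen$stream)
  }
})

test_that("depth and alphabet caps are respected exactly", {
  gen <- genSegmentationCorpus(n_words = 4, word_len = 3, n_tokens = 200, seed = 3)
  for (d in 0:2) expect_lte(nLevels(buildHierarchy(list(gen$stream), max_depth = d)) - 1L, d)
  # a cap below the surface alphabet (12 phonemes) is rejected outright
  expect_error(buildHierarchy(list(gen$stream), max_depth = 3, max_alphabet = 3),
               "exceeds")
  # a cap admitting the surface and the 4 words, but not the many level-2
  # chunk types, stops growth after level 1
  memCap <- buildHierarchy(list(gen$stream), max_depth = 3, max_alphabet = 12)
  expect_equal(nLevels(memCap), 2)
  expect_true(all(vapply(levelModels(memCap), function(m)
    length(alphabet(m)), integer(1)) <= 12))
  expect_error(buildHierarchy(list(gen$stream), max_depth = -1), "max_depth")
  expect_error(buildHierarchy(list(gen$stream), max_alphabet = 0), "max_alphabet")
})

test_that("each built level is strictly shorter than the one below", {
  gen <- genSegmentationCorpus(seed = 14)
  mem <- buildHierarchy(list(gen$stream), max_depth = 4)
  lens <- vapply(seq_len(nLevels(mem)) - 1L, function(d)
    sum(vapply(levelStreams(mem, d), nrow, integer(1))), numeric(1))
  expect_true(all(diff(lens) < 0))
})
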