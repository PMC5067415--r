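---
title: "Learning what happens next, and when: hierarchical sequence models with temporal expectation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Learning what happens next, and when}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhythmics)
```

# The model

`rhythmics` implements a statistical listener. Its input is a stream of
discrete events — phonemes, drum strokes, melodic onsets — each carrying a
symbol and an onset time in milliseconds. The listener learns two coupled
things from exposure:

1. **What comes next.** A Markov transition model per hierarchy level
   (first-order by default) turns each context into a predictive
   distribution over the alphabet. From that distribution we take the two
   standard information-theoretic readings: the *information content*
   (surprisal, $-\log_2 p$) of the symbol that actually arrives, and the
   *entropy* of the prediction itself. All logarithms are base 2; all
   quantities are in bits.

2. **When it comes.** For every transition (context $\to$ symbol) the model
   accumulates a histogram of the inter-onset interval (IOI) between the
   context's last event and the continuation, on a 20 ms grid. The pair
   (transition probabilities, per-transition holding-time densities) is a
   Markov renewal process: the chain says what, the holding times say when.

On top of these two learners sit four derived behaviours: chunking into a
layered memory, metrical expectation profiles, entrainment (tapping), and a
geometric meter space. Each is described below with the design decisions it
embeds.

## Chunking and the layered memory

A perceptual buffer fills symbol by symbol. A chunk boundary is declared
*before* the current symbol when its information content rises by more than
`theta` bits over the previous symbol's (default `theta = 0`), or when the
buffer reaches `max_len` symbols (default 16, a guard against pathological
streams with no surprisal structure). The rise rule is deliberately online —
no lookahead — because the listener it models is online. A peak-picking rule
with lookahead would find the same boundaries on clean segmentation streams
but would not be incremental.

Chunks are labelled by exact match: identical member sequences always get
the same next-level symbol, minted in first-encounter order, so labelling is
deterministic and two runs over the same corpus are isomorphic.
Similarity-based merging of near-identical chunks (consolidation) is a
known omission: nothing in the present design optimizes category membership
after the fact.

`buildHierarchy()` iterates train → chunk → label per level, batch-wise: the
transition model for level $k$ is trained on the complete level-$k$ stream
before level $k+1$ is built. A fully incremental variant (retrain after
every chunk) would be closer to a live listener but non-deterministic under
reordering; batch retraining was chosen for determinism and testability.
Building stops at `max_depth`, when a level stops compressing, or when the
next level's alphabet would exceed `max_alphabet`. The two caps are exposed
as first-class parameters because limiting memory depth and alphabet size
is itself a scientifically interesting manipulation (a model of limited
cortical resources: with one chunking layer, words are memorable but
two-word phrases have no single symbol; with two layers they do).

The invariant that makes the memory trustworthy is exact reconstruction:
expanding the labels at any level through the registries reproduces the
surface stream byte for byte. This is enforced by the class validity method
and tested property-style over seeded corpora.

## Temporal densities and the 20 ms grid

Holding-time densities are histograms on a half-open grid of 20 ms bins.
20 ms is the approximate minimum interval at which listeners can reliably
report the order of two onsets, so a finer grid would model precision the
ear does not have; a coarser one would blur eighth notes at fast tempi. The
densities are kept as raw counts and normalized on read. Smoothing is a
small uniform mass floor (`floor_mass = 1e-4` spread over the grid) rather
than a kernel: it keeps surprisal finite for never-seen timings without
distorting the shape of well-observed densities. Gaussian kernel smoothing
was considered and rejected as a default because the study corpora are
grid-aligned and the kernel only blurs them; it can be revisited for
expressive (non-quantized) data.

The *instantaneous* distribution at time $t$ since the last event fuses the
two learners by product-then-renormalize:

$$P(s \mid \text{context}, t) \;\propto\; P(s \mid \text{context}) \cdot
f_{\text{context},s}(t)$$

The product form is this package's choice — it is the na\"ive Bayes
combination of the two sources, reduces to the sequence model when all
densities are flat, and makes timing decisive exactly when temporal supports
are disjoint. If every product is zero the sequence distribution is returned
unchanged (and a message emitted), so the fallback is explicit rather than
silent.

## Expectation profiles and metrical strength

The metrical expectation profile answers: given a reference event at time 0
(a bar start), how strongly is an onset expected in each 20 ms bin of the
next few seconds, and from which level of the hierarchy does that
expectation come?

Per level, the profile is the expected-onset density of the level's Markov
renewal process, propagated forward from an anchor: mass $m$ at (symbol
$s$, bin $t$) spreads to $(s', t+d)$ with weight $P(s'\mid s) \cdot
f_{s\to s'}(d)$, and the per-bin arrivals are accumulated over passes. For a
deterministic period $p$ this yields unit mass at $p, 2p, 3p, \dots$ — the
additive-cycle picture of meter. The anchor state is the empirical
distribution of stream-initial symbols at that level, which is a bar start
in the generated corpora because streams are generated bar-aligned.

The combined profile is the plain, unweighted sum over levels. Two
alternatives were considered: per-level normalization before summing, and
learned per-level weights. Neither is adopted by default — per-level
strengths are already commensurable (probability mass per bin), and
unweighted addition is the simplest hypothesis for how coinciding
expectations reinforce. `level_weights` exists for exploration.

A *loud rest* is a bin whose combined strength reaches the threshold
(default: half the maximum combined strength, the usual half-height
peak-picking convention) but contains no onset. Onsets are interpreted
relative to the first onset, making detection invariant under global time
shifts, and only bins up to the last onset are candidates — expectation
beyond the end of the stimulus is unfulfilled future, not a rest.

## Entrainment

The tapper is a minimal phase-correction model: it takes a period (directly,
or as the earliest half-height peak of an expectation profile), anchors its
phase at the first observed onset, and after every onset corrects its next
prediction by `gain` × (observed − predicted), with `gain` in $[0,1]$. On
isochronous input with a correct period the signed error therefore contracts
exactly as $(1-\text{gain})^k$ — a closed form the tests check digit for
digit. Zero gain disables correction and the tapper drifts with any tempo
change; gain 1 snaps to the last onset. No oscillator dynamics are modelled:
at this level of abstraction an oscillator is a repeatedly triggered timer,
and the timer is the period parameter.

Two further behaviours fall out of the same machinery rather than being
programmed in. A model trained on a 2+2+3 (7/8) corpus produces a profile
whose maxima sit on the 2+2+3 grid — non-isochronous entrainment is learned
from exposure, not forced by an isochronous oscillator. And a model trained
on 4/4, fed a 7/8 stream, shows a surprisal spike at every shortened cycle:
the long-group interval that closes the 7/8 bar has essentially no mass
under the 4/4 model's holding-time densities, which is the "jolt" a
Western-enculturated listener reports.

## The meter space

Metrical structures are embedded as points in a quality-dimension space:
one dimension per hierarchical level holding its subdivision ratio, with an
additively grouped level (the 2+2+3 of 7/8) contributing its normalized
group-length vector on one domain, and an optional tempo dimension carrying
the basic unit in ms. This concrete encoding is the package's own proposal:
it is the smallest representation in which the periodic components of a
meter are coordinates, similarity is distance, and tempo abstraction is a
projection. Distance is Euclidean within a domain and city-block across
domains (integral vs. separable dimensions); optional per-dimension scaling
models salience shifts and is off by default.

Timing diagnosis works on ordered sets of performances of one regularized
rhythm, each a vector of signed per-onset deviations. Three statistics are
computed: the largest per-position mean deviation (displacement of the
cluster), the pooled within-position standard deviation (its spread), and
the Spearman correlation of per-performance deviation magnitude against
performance index (its trajectory). The decision rule tests tempo change
first (trend $\ge$ 0.8), because a drift also inflates dispersion; then
groove (displacement > 8 ms with dispersion < 15 ms); anything else is an
inconsistent-error cloud, including the degenerate tight-cluster-at-zero
case, for which "no consistent displacement, no trend" is the least wrong
of the three labels. The 8/15/0.8 defaults are order-of-magnitude choices
(just-noticeable displacement, typical motor jitter, strong monotonicity)
and all three are parameters.

# The synthetic corpora

The generators produce the study conditions; they are first-class, tested
code.

* **Metrical rhythms** (`genMeterCorpus`): onsets on a metrical grid by
  independent Bernoulli draws whose probability decreases strictly with
  decreasing metrical strength — defaults 1.0 (downbeat), 0.85 (mid-bar),
  0.65 (beats 2/4), 0.2 (offbeat eighths), the asymmetry from which meter is
  learnable. Each event carries its strength-class symbol (`db`, `mb`,
  `bt`, `ob`), standing in for the accentual/timbral cues (bass drum,
  snare, hi-hat; melodic accent) that mark metrical position in real music.
  In the 7/8 template the long-group start carries its own class, as Balkan
  practice accents it differently from the short-group start. The basic
  unit defaults to 240 ms (an eighth at 125 bpm), chosen as a multiple of
  the 20 ms quantum so grid positions coincide with analysis bins; with a
  non-divisible unit the binning drifts through the renewal convolution and
  smears the profile. What these corpora do **not** emulate: expressive
  timing, dynamics, polyphony, or any correlation between successive
  Bernoulli draws — so passing tests show the machinery recovers designed
  statistical structure, not that it parses real performances.

* **Segmentation streams** (`genSegmentationCorpus`): an artificial lexicon
  of `n_words` words × `word_len` symbols (all symbols distinct across
  words), concatenated by uniform random choice. Within-word transition
  probability is 1, between-word 1/`n_words`, so surprisal rises exactly at
  word joins. Real lexicons share phonemes across words and have Zipfian
  frequencies; this generator isolates the boundary-entropy signal in its
  cleanest form.

* **Performance sets** (`genPerformanceSet`): groove = +15 ms on the
  backbeats with 3 ms jitter; inconsistent error = zero-mean 25 ms jitter;
  tempo change = deviation magnitude growing 2 ms per performance with 3 ms
  jitter. The values sit either side of the diagnosis thresholds by design —
  they are the textbook signatures, not hard cases.

* **Meter-space exemplars** (`genMeterExemplars`): per exemplar, level
  ratios and group proportions are re-estimated from spans jittered by
  `sigma_ms` (default 10 ms), so each point is what a listener would
  estimate from one noisy performance. All templates are embedded in the
  union of their dimension sets, with absent dimensions at zero.

Every generator requires a seed, and one top-level seed is expanded into
per-stage sub-seeds by hashing the stage name (`stageSeed`), so identical
configurations reproduce bit for bit and stages can be re-run independently.

# Study problem sizes and numerical choices

The packaged studies use: 20 streams × 16 bars for the 4/4 corpus (about
1300 events), 300 word tokens for segmentation, 500 events for renewal
recovery, 40 exemplars × 4 classes for classification, 50 performance sets
× 3 kinds for diagnosis, hierarchies of depth ≤ 3, and profiles over a
4000 ms horizon (two 4/4 bars) on the 20 ms grid. These sizes are large
enough that the measured properties are stable across seeds and small
enough that the whole suite runs in well under a minute.

Numerical conventions: distributions must sum to 1 within 1e-9 (enforced);
grid bins are half-open `[t, t+q)` and times map to bins by floor; chunk
spans are half-open index intervals; nearest-neighbour ties break to the
alphabetically earliest label, then the earliest point; profile peak ties
break to the earliest time. Degenerate inputs are errors, not guesses:
empty models cannot predict, zero-mass symbols have no finite surprisal
(the error message points to smoothing), unseen transitions have no density
unless smoothing is on.

# Known limitations

* Viewpoints are modelled independently; the only cross-viewpoint coupling
  is shared chunk boundaries. No fusion rule for multidimensional
  prediction is implemented.
* Chunk labelling is exact-match; no consolidation phase.
* The boundary rule is single-reading: no lattice of alternative parses is
  maintained, so the "competition among parallel generators" reading of
  buffer flushing reduces to the rise rule here.
* The meter space covers periodic components only (ratios and group
  vectors); richer spaces with onset-salience dimensions are out of scope,
  and published classification figures obtained on external dance-music
  corpora with such spaces are not comparable to the synthetic-genre
  accuracy reported by the acceptance script.
* Higher hierarchy levels built from small corpora have large, sparse
  alphabets and contribute noisy expectation mass; the `max_alphabet` cap
  is the instrument for keeping them out of a study.

# A worked pass through the pipeline

```{r pipeline, eval = FALSE}
corpus <- genMeterCorpus(seed = 7)                 # 4/4, 20 streams x 16 bars
memory <- buildHierarchy(corpus, max_depth = 3)    # layered chunk memory
profile <- expectationProfile(memory, horizon_ms = 4000)
profile                                            # peak at the next downbeat

rock <- 240 * c(0, 2, 3, 6, 8, 10, 12, 14)         # two-bar rock pattern
detectLoudRests(profile, rock)                     # 960: the unplayed mid-bar

taps <- entrain(profile, 480 * 0:10, gain = 0.5)   # tap along at the beat
phaseErrors(taps)
```
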