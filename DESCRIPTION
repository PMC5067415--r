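Package: rhythmics
Title: Hierarchical Statistical Sequence Learning and Temporal Expectation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for modelling how a statistical listener learns both what
    happens next and when it happens in symbolic event streams such as music
    and speech. Provides Markov transition models with information-theoretic
    measures, online chunking of streams into a layered hierarchical memory,
    per-transition inter-onset-interval densities on a millisecond grid
    (a Markov renewal view of rhythm), additive multi-level metrical
    expectation profiles with loud-rest detection, a phase-correcting
    entrainment (tapping) simulator, and a geometric conceptual space of
    meter for nearest-neighbour rhythm classification and timing diagnosis.
    Includes seeded synthetic-corpus generators for metrical rhythms,
    word-segmentation streams, and performance timing sets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'distributions.R'
    'transitions.R'
    'chunking.R'
    'temporal.R'
    'profile.R'
    'entrain.R'
    'meter-space.R'
    'generators.R'
    'io.R'
    'cli.R'
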