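Package: ddmarker
Title: Dynamic Digital Markers from Two-Time-Scale Markov Chains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for deriving dynamic digital markers from daily digital
    phenotyping streams. Models a patient's day-by-day biobehavioural
    trajectory as a two-time-scale Markov chain over slow clinical
    macro-states and fast behavioural micro-states, and computes
    first-order (stationary occupancy), second-order (entropy rate) and
    third-order (macro-centric entropy rate, mixing time, recurrence time)
    markers, both analytically and by finite-window plug-in estimation.
    Includes symbolization of raw numeric streams (ordinal patterns,
    approximate entropy, Lempel-Ziv complexity, block entropy), seeded
    trajectory simulation, an interpretable chain generator, and
    entropy-based regime-shift detection with permutation-calibrated
    CUSUM and binary segmentation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    graphics,
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
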