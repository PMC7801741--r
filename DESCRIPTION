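Package: planspike
Title: Spike-Train Similarity, Tuning, Latency and Decoding Analysis for
    Cued Action-Planning Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for trial-aligned extracellular spike trains
    recorded during instructed-delay, multi-modal cued movement tasks.
    Implements the Victor-Purpura spike-train edit distance with its
    temporal-precision calibration, spike train similarity space (SSIMS)
    embeddings of single-trial ensemble activity with normalized
    within/between-category distance statistics, sliding-window
    responsive/selective classification of single units, response-onset
    latency estimation from runs of significant bins, context-dependent
    aural encoding tests, and sliding-window population decoding with
    permutation-based chance bands. Includes an inhomogeneous-Poisson
    synthetic ensemble generator emulating the task structure (sequential
    and simultaneous audio-visual cueing plus passive listening) with
    known ground truth for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Rtsne,
    e1071,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
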