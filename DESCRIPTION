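Package: neurostat
Title: Autonomous DO-Stat Fed-Batch Fermentation Control with Neural
    Baseline Recognition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and testing an autonomous dissolved-oxygen
    (DO) stat feeding controller for fed-batch Escherichia coli
    cultivation. Provides a synthetic generator of labeled DO windows that
    emulates DO-stat dynamics (depletion spikes, post-feed declines,
    drifting baselines), a multilayer-perceptron regressor that recognizes
    the DO baseline from 60-minute sliding windows, causal Savitzky-Golay
    smoothing of the recognized baseline stream, the full baseline-relative
    control logic (oxygen-supply adaptation, pulsed glucose feeding with a
    safety cutoff, latched nitrogen feeding, time-triggered induction with
    phase-specific parameter sets), a minimal fed-batch plant simulator for
    closed-loop exercise of the controller, and Taguchi-style range
    analysis of orthogonal induction-optimization experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    tools,
    utils,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
LinkingTo:
    Rcpp,
    RcppArmadillo
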