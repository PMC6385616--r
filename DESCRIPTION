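Package: betarebound
Title: Simulation and Statistical Analysis of Movement-Related Beta-Band
    Oscillations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying event-related desynchronization and the
    post-movement beta rebound in sensor-level MEG/EEG recordings. Provides a
    synthetic-data generator for event-locked oscillatory recordings with
    planar-gradiometer-like channel pairs, EMG and accelerometer side
    channels; preprocessing (epoching, peak-to-peak artifact rejection,
    accidental-movement detection, evoked-response subtraction, EMG
    conditioning); Morlet-wavelet time-frequency decomposition with
    log-baseline correction and peak-channel selection; cluster-based
    permutation inference for independent, paired, and pseudo-2x2 interaction
    designs on time-frequency grids and 1-D time courses; and default-prior
    Bayes factors (Jeffreys-Zellner-Siow t-tests and regressions,
    Dirichlet-multinomial contingency tests) for subject variables, trial
    counts, and baseline-power model comparisons. An orchestration layer runs
    the full simulate-preprocess-decompose-test workflow and writes
    machine-readable reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    jsonlite,
    Rcpp,
    signal,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
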