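Package: megnets
Title: Multiscale Entropy and Frequency-Band Network Analysis of Epoched
    MEG-Like Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for multiscale analysis of epoched multichannel
    electrophysiological recordings. Sensor time series are resampled and
    decomposed into four dyadic wavelet bands (theta, alpha, beta, low
    gamma) with a maximal overlap discrete wavelet transform; per-trial
    Shannon wavelet entropy and normalized mutual information connectivity
    are estimated within and between bands; weighted matrices are converted
    to nested binary graphs over a network-density sweep and summarized
    with twelve graph diagnostics (efficiency, clustering, betweenness,
    modularity, hierarchy, synchronizability, assortativity, attack
    robustness, connection distance, Rentian scaling) plus cost-efficiency;
    and groups are compared with permutation tests,
    functional-data-analysis curve tests, false-discovery-rate control, and
    a repeated-measures analysis of trial-to-trial network variability. A
    seeded generator of two-group synthetic cohorts with controllable band
    coupling, cross-frequency coupling, waveform regularity and trial
    variability supports calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    igraph,
    ggplot2,
    optparse
Config/testthat/edition: 3
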