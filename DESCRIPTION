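Package: optoplace
Title: Opto-Tagging Classification and Spatial-Coding Analysis for
    Juxtacellular Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis toolkit for single-cell juxtacellular recordings from
    hippocampal CA1 during free exploration with optogenetic tagging.
    Implements latency-based opto-tag classification of directly versus
    synaptically light-activated neurons (peristimulus time histograms,
    per-trial first-spike latencies, pulse-inclusion filtering),
    electrophysiological cell typing (mean rate, burst index), and spatial
    modulation quantification (Gaussian-kernel occupancy and firing-rate maps,
    Skaggs spatial information, sparsity, trajectory linearization onto a
    best-fit ellipse, lap counting, and split-half rate-map stability).
    Includes a synthetic-data generator producing inhomogeneous-Poisson place
    cells on an O-shaped maze with ground-truth labels, a plain-text session
    interchange format, and nonparametric group statistics for cohort
    comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
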