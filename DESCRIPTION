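Package: circuitmapr
Title: Patch-Clamp Feature Extraction and Optogenetic Circuit-Map Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative analysis of optogenetic circuit-mapping
    experiments in cortical slices: extraction of passive membrane properties
    and the hyperpolarization-activated (I_h) sag-current slope from
    voltage-clamp step recordings, evoked postsynaptic current and potential
    metrics (charge, amplitude, onset latency), action-potential features
    (phase-plane threshold, depolarizing afterpotential, regular- versus
    burst-spiking mode), a one-dimensional max-margin classifier on the I_h
    slope with cross-validation and a shuffled-label null, layer-by-cell-type
    input-map assembly with activation criteria and convergence statistics,
    Patch-seq count-matrix quality control and differential-expression
    gating, and laminar axon-fluorescence profiling. A seeded synthetic-data
    simulator generates every input the pipeline consumes, so all stages are
    testable without recordings or sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    pracma,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
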