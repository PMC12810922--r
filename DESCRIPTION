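Package: mitofast
Title: Flow-Cytometry Segregation Tracking and Stochastic Nucleoid
    Simulation for Yeast mtDNA Quality Control
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantitative machinery for studying mitochondrial DNA (mtDNA)
    heteroplasmy segregation in budding yeast. Provides the FAST
    flow-cytometry gating classifier (forward-scatter debris gate, kernel
    density estimation of the fluorescence channel, two-peak/valley
    detection, and classification into dark, heteroplasmic and fluorescent
    fractions), an agent-based simulator of nucleoid segregation in a
    growing cell population with heteroplasmy-coupled division probability,
    estimators for exponential growth rate and doubling time, fluorescence
    decay half-life and qPCR relative mtDNA copy number, a Monte-Carlo
    resampling test with Fisher combination for comparing simulations to
    flow-cytometry measurements, mitochondrial network skeleton metrics on
    vertex tables, and synthetic-data generators with planted ground truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
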