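Package: fluorcount
Title: Unbiased Fluorophore Counting from Blinking Time Traces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates absolute fluorophore numbers from single-marker-
    switching (GSDIM/dSTORM) fluorescence time traces using a hidden
    two-timescale Markov model of photoswitching. Provides a simulator for
    per-region intensity traces and synthetic camera movies with EMCCD noise,
    polynomial background correction with per-region offset calibration, a
    Gaussian-process pseudo log-likelihood estimator of the fluorophore
    number and photokinetic parameters, a simplified first-frame estimator
    based on single-molecule blink brightness, and characterization tools
    (excess relative variance, dwell-time dark-state counting, weighted
    multi-exponential decay fits, conditional-binomial labeling-yield fits).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    rlang,
    ggplot2,
    generics,
    readr,
    jsonlite,
    tiff,
    minpack.lm,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), optparse, yaml, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
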