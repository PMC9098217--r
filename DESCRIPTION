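Package: prwsearch
Title: Finite-Length Persistent Random Walk Models of Cellular Protrusion Target Search
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and inference for finite-length persistent random walk
    (PRW) searches, motivated by airinemes: long, thin signalling protrusions
    that zebrafish pigment-cell precursors extend toward target melanophores.
    Provides a fast Monte-Carlo simulator of constant-speed searchers with
    diffusing heading and an absorbing disk target; closed-form ballistic and
    PDE diffusive reference limits for validation; trajectory estimators
    (mean squared displacement with power-law fits, step-length CCDF tail
    fits, final-angle isotropy tests, tangent-angle autocorrelation and a
    maximum-likelihood estimator of the angular diffusion coefficient);
    Fisher-information measures of the directional cue a contact delivers;
    parameter sweeps locating the contact-probability-optimal curvature; and
    Pareto trade-off analysis between search success and directional
    information. Includes a synthetic-data generator emulating digitized
    live-cell trajectory datasets and a model-convolution image renderer.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
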