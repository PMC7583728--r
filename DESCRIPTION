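Package: patchseg
Title: Segmentation-Based Idealization of Single-Channel Patch-Clamp Traces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Headless pipeline for detecting, timing, sizing and kinetically
    characterizing opening and closing transitions in whole-cell unitary
    current recordings. Combines a windowed running-median filter and
    derivative-threshold candidate detection with total variation denoising
    for precise transition localization, error-function step fitting for
    amplitudes and transition time constants, iterative baseline drift
    correction against four drift families, and gating statistics (nominal
    open probability, conductance histogram decomposition, subconductance
    ratios, transition-kinetics distributions). Includes a ground-truth
    simulator of multi-state, multi-channel gating for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    graphics,
    Rcpp,
    minpack.lm,
    data.table,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
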