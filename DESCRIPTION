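Package: plasmotrap
Title: Velocimetry and Accumulation Kinetics for Plasmo-Thermal Bacterial Trapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Analysis pipeline for transmitted-light microscopy recordings of
    bacterial accumulation at a heated plasmonic optical fiber tip.
    Quantifies accumulation kinetics from region-of-interest concentration
    traces (exponential-decay and Gaussian profile fits), measures in-plane
    bacterial velocities by frame-by-frame track fitting, maps wide-area
    speeds with temporal laser-speckle-contrast velocimetry calibrated
    against the tracked velocities, and computes the supporting transport
    physics (Rayleigh, Stokes and Reynolds numbers, Stokes drag, Soret
    coefficient). Includes a seeded synthetic-video generator that emulates
    the recordings with known ground truth for end-to-end validation.
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
    minpack.lm,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
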