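Package: matrixage
Title: Multimodal Optical Characterization of Different-Age Collagen 3D Matrices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing type I collagen 3D matrices prepared from
    collagens of different donor ages (newborn, young adult, old adult) with
    label-free optical readouts. Implements a Monte Carlo photon-transport
    forward model of spatially-resolved diffuse reflectance with look-up-table
    inversion into reduced scattering spectra, turbidity kinetics analysis of
    collagen fibrillogenesis, skeleton-based fiber morphometry of confocal
    reflectance stacks, ATR-FTIR band-ratio glycation markers, and a synthetic
    data generator encoding per-age presets with known ground truth for
    end-to-end validation of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    minpack.lm,
    EBImage,
    tiff,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
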