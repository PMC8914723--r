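Package: nirfm
Title: Foreign-Material Discrimination in Fresh-Cut Vegetables from NIR Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Chemometric toolkit for detecting foreign materials (plastics,
    wood, paper, insects, metal, stone, rubber) mixed into fresh-cut
    vegetables from near-infrared absorbance spectra. Provides spectral
    preprocessing (normalization, standard normal variate, multiplicative
    scatter correction, Savitzky-Golay derivatives), NIPALS PLS-DA
    classification with a 0.5 decision baseline, five multispectral
    waveband-selection algorithms (weighted regression coefficients,
    variable importance in projection, sequential forward selection,
    successive projections, forward interval PLS), per-pixel classification
    of line-scan multispectral image cubes with object-level detection
    scoring, and a seeded synthetic-data generator for labeled spectra and
    ground-truthed hypercube scenes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    signal,
    stats,
    utils,
    withr,
    png,
    EBImage
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
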