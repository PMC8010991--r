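Package: nirherit
Title: Near-Infrared Spectral Calibration and Half-Sib Genetic Analysis of
    Leaf Nutrition Traits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline linking leaf near-infrared (NIR)
    reflectance spectra to tree-breeding decisions. Simulates balanced
    half-sib progeny trials with genetically structured anthocyanin (ANTH),
    flavonoid (FLAV) and nitrogen-balance-index (NBI) traits and
    trait-linked absorbance spectra; implements standard-normal-variate and
    Savitzky-Golay derivative preprocessing, partial least squares
    regression (PLSR) with leave-one-out component selection, four
    wavelength-selection algorithms (sMC, iterative predictor weighting,
    regularized backward elimination, genetic algorithm), a repeated
    80/20 calibration/validation protocol with ensemble prediction, and
    half-sib quantitative genetics: REML variance components, narrow-sense
    heritability, genetic and phenotypic correlations, BLUP family breeding
    values, realized genetic gain and multi-trait family selection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    Rcpp,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    signal,
    testthat (>= 3.0.0),
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Config/testthat/edition: 3
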