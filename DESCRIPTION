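Package: rotospec
Title: Rotational Hyperspectral Imaging Chemometrics for Fruit Quality
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end chemometrics pipeline for predicting internal
    quality traits of fruit (starch, vitamin C, soluble solids, titratable
    acid) from rotational hyperspectral images. Provides ENVI cube input and
    output, dark/white reflectance calibration, region-growing extraction of
    a fruit region of interest, nine spectral preprocessing transforms
    (Savitzky-Golay and moving-average smoothing, min-max normalisation,
    multiplicative scatter correction, baseline correction, standard normal
    variate, detrending, first and second Savitzky-Golay derivatives), three
    wavelength-selection algorithms (genetic algorithm, successive
    projections algorithm, competitive adaptive reweighted sampling),
    calibration models (support vector regression, principal component
    regression, partial least squares regression, multiple linear
    regression), coefficient significance mapping, and a seeded synthetic
    data generator that emulates the rotational acquisition protocol so the
    whole pipeline is testable without instrument data.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    signal,
    e1071,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
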