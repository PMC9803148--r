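Package: ramgrade
Title: Raman Microspectroscopy Grading of Radiation-Induced Lung Toxicity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end chemometrics pipeline for grading radiation-induced
    murine lung toxicity from dispersive Raman microspectroscopy maps.
    Provides preprocessing of raw spectra (window cropping, shape-preserving
    axis interpolation, Savitzky-Golay smoothing, iterative peak-stripping
    baseline estimation, area normalization, and phenylalanine-band peak
    alignment), basis-restricted non-negative matrix factorization against
    fixed tissue/mixed/media basis spectra for removing air-pocket and
    media-contaminated spectra, and multinomial LASSO logistic regression over
    fibrosis and pneumonitis grades with stratified 10-fold cross-validation
    and the one-standard-error rule. A synthetic spectral-map generator with
    known mixing weights, baselines, and grade-dependent collagen signal makes
    every stage testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
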