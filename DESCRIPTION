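Package: oprs
Title: Oblique Polarized Reflectance Spectroscopy Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for multifiber oblique polarized reflectance
    spectroscopy (OPRS) of epithelial tissue: calibration-based preprocessing of
    six-channel polarized reflectance spectra, patient standardization against
    normal-site measurements, a 120-entry spectral feature catalogue with
    Welch-t discriminatory wavelength selection, minimum-redundancy
    maximum-relevance feature selection with grouped leave-one-subject-out
    cross-validated tree-ensemble classification, nonparametric ROC analysis and
    a permutation overtraining test, plus phantom depth-penetration calibration.
    Includes a two-layer tissue/probe forward model that simulates complete
    cohorts of raw measurements so the full pipeline can be exercised and tested
    without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    pracma,
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
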