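Package: sorgspec
Title: Chemometric Calibration and Grading of Sorghum Grain Composition
    from FT-NIR Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native workflow for calibrating near-infrared
    (4,000-10,000 cm-1) absorbance spectra of sorghum grains against
    wet-chemistry reference values of eight biochemical components (starch,
    protein, fat, tannin, cellulose, hemicellulose, lignin, ash). Provides
    spectral pretreatments (multiplicative scatter correction, standard
    normal variate, Savitzky-Golay smoothing and derivatives), deterministic
    calibration/validation partitioning (Kennard-Stone and SPXY),
    competitive adaptive reweighted sampling (CARS) wavelength selection,
    PCA-score outlier screening, NIPALS partial least squares regression
    with leave-one-out cross-validation, RPD-based model adequacy ratings,
    NREL composition formulas, and threshold rules that grade grains for
    food, feed, or fuel use. A seeded synthetic-spectra generator emulates
    the statistical structure of a 98-sample sorghum panel so the whole
    pipeline is testable without instrument data.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
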