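Package: osmoquant
Title: Sulfur-Isotope-Guided Screening and Quantification of Algal
    Osmolytes in LC-HRMS Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Discovery and targeted quantification of sulfur-containing
    osmolytes (such as cysteinolic acid) in centroided liquid
    chromatography high-resolution mass spectrometry data.  Provides an
    exact-mass and isotope-pattern engine, a seeded synthetic LC-HRMS run
    generator for validation, chromatographic feature detection with
    sulfur M+2 isotopologue flagging, salinity up-regulation screening,
    tandem-MS neutral-loss fragment annotation, external calibration with
    limits of detection and quantification, normalization of extract
    concentrations to per-cell amounts and intracellular molarity, and
    condition statistics (fold changes, one-way ANOVA with Tukey
    comparisons).
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
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    mzR,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
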