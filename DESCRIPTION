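Package: desirsm
Title: Response-Surface Optimization, Desirability Analysis and
    Polyphenol Assay Arithmetic for Designed Extraction Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for optimizing extraction conditions by response surface
    methodology: central composite design construction and factor coding,
    second-order polynomial fitting with full ANOVA diagnostics (pure error,
    lack of fit, coefficient of variation, adequate precision), Derringer
    desirability multi-response optimization with RSD-based validation,
    calibration-curve and IC50 assay arithmetic, chemometric post-analysis
    (Pearson correlation, correlation-matrix PCA, hierarchical clustering),
    and monoisotopic mass and neutral-loss annotation of ESI-MS peak tables.
    Includes seeded synthetic-data generators for every analysis stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    jsonlite,
    yaml,
    generics,
    minpack.lm,
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
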