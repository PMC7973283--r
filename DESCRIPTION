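Package: bapanel
Title: Stepwise Optimization of Aging Biomarker Panels for Biological Age
    Assessment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and evaluates panels of aging biomarkers for biological
    age (BA) estimation from cross-sectional cohort tables. Biomarkers are
    screened by correlation with chronological age, pruned for redundancy
    using cross-correlations, scored by their achievable accuracy in years
    (instrument accuracy relative to the biomarker's change over a reference
    age interval), and calibrated by fitting and algebraically inverting
    biomarker-on-age regressions to obtain partial biological ages. Extreme
    biomarker values are rejected by a per-decade sigma rule, and the final
    BA is a weighted mean of partial biological ages with cohort-level
    quality statistics (mean and standard deviation of BA-CA, correlation of
    BA with CA). Includes a synthetic cohort generator with controllable age
    slopes, noise, cross-correlations, missingness and planted outliers for
    validating every stage of the pipeline.
License: MIT
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
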