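Package: sebovol
Title: Sebum Volatilome Marker Discovery with Sparse PLS-DA
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for volatile-compound (GC-MS headspace)
    feature matrices from sebum swabs, aimed at discovery of disease
    markers in Parkinson's disease and its prodromal stage (isolated REM
    sleep behaviour disorder).  Provides system-suitability QC by relative
    standard deviation, annotation filtering, total-ion-count
    normalisation with log transform and autoscaling, a from-scratch
    sparse partial least squares discriminant analysis (sPLS-DA) with
    variable importance in projection (VIP) scores, grid-search tuning
    and feature-stability scoring under repeated stratified
    cross-validation, screens for group-intermediate and longitudinally
    regulated features, and a constrained random-forest battery for
    confounder assessment.  A synthetic-data module generates feature
    matrices with planted ground truth so every stage is testable without
    instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    ranger,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    withr,
    optparse
Config/testthat/edition: 3
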