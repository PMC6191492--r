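Package: glialarray
Title: One-Color Microarray Differential Expression Pipeline for Paired
    Glial Cell Contrasts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of one-color (Agilent Feature
    Extraction style) microarray experiments contrasting a treatment
    against a medium control in two cell types. Provides feature-level
    quality filtering and on-chip replicate collapsing by geometric mean,
    quantile normalization with global linear scaling to a reference 75th
    percentile, surrogate flooring of low intensities, empirical-Bayes
    moderated t-tests with Benjamini-Hochberg correction, cross-cell-type
    four-way classification of differentially expressed genes, volcano and
    heat-map table preparation, delta-delta-Ct qPCR quantification, and a
    synthetic-data generator with known differential-expression truth for
    validation of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    limma,
    jsonlite,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
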