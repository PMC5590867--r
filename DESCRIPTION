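Package: indexminer
Title: Mining PCA-Loading-Weighted Indices Against Discrete-Time Mortality
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Constructs every cumulative, principal-component-loading-weighted
    index from a survey dataset's variables and screens each index for
    association with second-year mortality using survey-weighted discrete-time
    event-history (person-period logistic) models. Includes a synthetic
    survey-cohort generator with MEPS-style reserved codes, redundancy and
    complex-sampling structure; preprocessing (reserved-code recoding,
    skewness-gated log transforms, Spearman redundancy filtering, chained
    imputation, dummy expansion, weighted standardization); survey-weighted
    principal component analysis; significance summaries by index size; and
    publication-impact arithmetic for the resulting volume of significant
    indices.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    e1071,
    sandwich
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
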