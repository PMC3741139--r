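Package: mmrsig
Title: Expression Signatures Discriminating Hereditary Colorectal Cancer by Mismatch-Repair Status
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for deriving and transferring mismatch-repair (MMR)
    status expression signatures in hereditary colorectal cancer cohorts. Provides
    detection-p-value feature filtering, cubic-spline and quantile normalization with
    plate scaling and batch-mean adjustment, a from-scratch implementation of two-class
    Significance Analysis of Microarrays (SAM) with permutation-based false discovery
    rate control, average-linkage hierarchical clustering on Pearson correlation
    distance, nearest-centroid classification of external cohorts after an RPKM
    harmonization recipe, Fisher's exact tests for clinical contrasts, and a seeded
    synthetic-cohort generator with planted differential expression for recovery-based
    validation.
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
    limma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
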