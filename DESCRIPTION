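Package: phenoforge
Title: EMR Computable Phenotyping with Interpretable Case Definitions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for developing and validating computable case
    definitions from multi-table primary-care electronic medical records.
    Engineers binary temporal code-prefix and bag-of-words features with
    negation filtering, trains F1-optimised classification trees under nested
    cross-validation with class rebalancing and feature reduction, simplifies
    the tree into an importance-ranked rule-based case definition, and reports
    full validity metrics (sensitivity, specificity, PPV, NPV with confidence
    intervals). Ships a synthetic cohort generator shaped like a primary-care
    sentinel-network extract so every stage is testable without access to
    confidential data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    rpart,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
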