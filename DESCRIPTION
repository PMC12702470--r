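Package: notephen
Title: Rule-Based Phenotyping from Free-Text Clinical Notes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A transparent, auditable rule-based pipeline for extracting
    patient-level phenotype flags from free-text clinical notes. Locates
    condition mentions with stem/synonym search patterns, classifies each
    mention's meaning in context (acute, historical, negated, under
    evaluation, different meaning) with an extensible cue-phrase library,
    drives an expanding-context review workflow for uncategorized mentions,
    exports per-patient binary datasets, and evaluates phenotyping accuracy
    (sensitivity and specificity with Wilson or t-based confidence
    intervals) against comparator labelings such as ICD codes. Includes a
    synthetic multi-note corpus generator with known ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
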