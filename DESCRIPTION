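Package: icdmine
Title: Apriori Mining of ICD-10 Comorbidity Association Rules from
    Longitudinal Hospital Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Turns longitudinal hospital diagnosis records into per-patient
    binary transaction databases and mines ICD-10 comorbidity association
    rules with a from-scratch Apriori frequent-itemset miner. Implements
    three-character ICD-10 category normalisation, chapter- and
    description-based code exclusion, single-hospitalization patient
    filtering, support/confidence/lift scoring, threshold filtering,
    confidence-descending sorting, and the cross-chapter versus
    within-chapter rule partition. Includes a seedable synthetic EMR
    cohort generator with planted association structure and closed-form
    expected metrics, so every pipeline stage is testable without access
    to real patient data.
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
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
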