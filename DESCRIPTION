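Package: ebpabench
Title: Benchmarking Personalised Conservative Treatment of Adolescent
    Idiopathic Scoliosis Against Randomised Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to evaluate an evidence-based personalised approach
    (EBPA) to conservative treatment of adolescent idiopathic scoliosis
    in longitudinal cohorts followed to the end of growth. Provides a
    cohort data model with validation and attrition accounting, a seeded
    synthetic cohort generator, a rule engine for treatment-intensity
    grading, guideline aims and over-/under-treatment classification,
    subgroup selection against the inclusion criteria of published
    end-of-growth randomised controlled trials, and effect measures
    (relative risk of success, number needed to treat, confidence
    intervals, chi-square, t-tests from summary statistics) under
    efficacy and worst-case intent-to-treat analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
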