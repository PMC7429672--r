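Package: cohortbridge
Title: Cross-Cohort Comparison, Propensity Score Matching and External
    Validation of Dementia Risk Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies systematic differences between two clinical cohorts
    via Bonferroni-adjusted interval comparisons, identifies comparable
    subjects with caliper-based propensity score matching (random or
    nearest-neighbour selection within the caliper, no replacement), builds
    a random-subsample null for the number of significant differences, and
    externally validates time-to-dementia risk models with Harrell's
    concordance index and time-dependent ROC AUC on full and matched
    validation cohorts.  Includes a synthetic two-cohort generator that
    emulates the demographic distribution shifts between large dementia
    cohort studies, with an exponential proportional-hazards survival
    mechanism and closed-form event-rate calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    xgboost,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
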