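#!/usr/bin/env Rscript
# Train the boosted time-to-dementia risk model on cohort A (CN+MCI) and
# validate it three ways: internal cross-validation on A, external
# validation on every eligible cohort-B subject, and matched validation on
# the B-side partners of 100 seeded matchings (matching on demographics
# plus baseline MMSE, no diagnosis stratification).

suppressPackageStartupMessages(library(cohortbridge))
dir.create("results", showWarnings = FALSE)
seed <- 20260928

A <- read_cohort_csv("results/cohort_A.csv")
B <- read_cohort_csv("results/cohort_B.csv")
feats <- c("age", "sex", "education_years", "apoe4", "mmse", "cdrsb",
           "hippocampus_volume", "entorhinal_volume", "ventricle_volume",
           "whole_brain_volume")
cfg <- pipeline_config()
train <- A[A$diagnosis %in% c("CN", "MCI"), ]

cat("internal cross-validation on cohort A (5-fold x 2 repeats) ...\n")
icv <- run_internal_cv(train, feats, cfg, learner = "boosted_cox",
                       k = 5, repeats = 2, seed = seed)
print(icv)

model <- fit_risk_model(train, feats, learner = "boosted_cox", seed = seed)

cat("external validation on all eligible cohort-B subjects ...\n")
ext <- run_external_validation(model, B, cfg)
print(ext)
write_validation_report(ext, "results/validation_external.json",
                        "results/auc_external.csv")

cat("matched validation over 100 matchings ...\n")
mat <- run_matched_validation(model, A, B, cfg, n_matchings = 100,
                              seed = seed + 1)
print(mat)
write_validation_report(mat, "results/validation_matched.json",
                        "results/auc_matched.csv")

cat(sprintf("\nC-index: internal %.3f | external full %.3f | matched %.3f (SD %.3f over %d matchings)\n",
            icv$c_index, ext$c_index, mat$c_index, mat$c_index_sd,
            mat$n_matchings))
cat("under the synthetic conditions (shared conditional hazard in both\n")
cat("cohorts) matching changes the evaluation population but not model\n")
cat("validity, so matched and full external performance are close; the\n")
cat("AUC(t) curves show the month-0 artifact as undefined entries.\n")
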