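#!/usr/bin/env Rscript
# Evaluate the caliper: (i) the classical single-covariate bias-reduction
# simulation at the full caliper sweep, and (ii) matched sample size vs.
# covariate balance on the synthetic cohorts, 100 matchings per caliper.
# This is the evidence behind the default caliper of 1 SD.

suppressPackageStartupMessages(library(cohortbridge))
dir.create("results", showWarnings = FALSE)
seed <- 20260928

calipers <- c(1.5, 1.3, 1, 0.7, 0.5, 0.3, 0.1)

cat("single-covariate bias-reduction simulation (200 replicates per caliper)\n")
bias <- do.call(rbind, lapply(calipers, function(cf) {
  sim <- simulate_bias_reduction(caliper_fraction = cf, n_reps = 200,
                                 seed = seed + round(100 * cf))
  data.frame(caliper = cf, mean_pct_bias_reduction = sim$mean_pbr,
             mean_matched_n = sim$mean_matched_n)
}))
print(bias, row.names = FALSE, digits = 4)
write.csv(bias, "results/caliper_bias_reduction.csv", row.names = FALSE)

cat("\ncaliper sweep on the synthetic MCI groups (100 matchings per caliper)\n")
A <- read_cohort_csv("results/cohort_A.csv")
B <- read_cohort_csv("results/cohort_B.csv")
mf <- c("age", "sex", "education_years", "apoe4")
sw <- caliper_sweep(A[A$diagnosis == "MCI", ], B[B$diagnosis == "MCI", ],
                    mf, calipers = calipers, n_repeats = 100, seed = seed)
print(sw, row.names = FALSE, digits = 3)
write.csv(sw, "results/caliper_sweep.csv", row.names = FALSE)
cat("\nsmaller calipers trade matched sample size for covariate balance;\n")
cat("wrote results/caliper_bias_reduction.csv, results/caliper_sweep.csv\n")
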