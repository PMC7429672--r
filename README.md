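# cohortbridge

Tools for asking — and answering — two questions that arise whenever a
clinical risk model meets a second cohort study:

1. **How different are the two cohorts?** Per diagnosis group, every
   jointly measured feature is compared with Bonferroni-adjusted confidence
   intervals (Welch intervals for means, Wald intervals for per-category
   proportions), and the number of significant differences found between
   *matched* sub-cohorts is contrasted with the number found between random
   subsamples of the same size — the random-subsample null — using a
   one-tailed Wilcoxon rank-sum test.
2. **What does the dissimilarity cost a risk model?** A boosted Cox model
   (gradient boosted trees on the partial-likelihood loss) predicting
   time-to-dementia conversion is validated internally (repeated k-fold
   cross-validation), externally on the full validation cohort, and on the
   matched subset, with Harrell's concordance index and the
   cumulative/dynamic time-dependent ROC AUC, AUC(t), over a monthly grid.

The bridge between the two is caliper-based propensity score matching: a
logistic model discriminates cohort membership, and subjects are matched
1:1 without replacement when their propensity scores differ by at most a
caliper `c · SD(score)`, with random (or nearest-neighbour) selection
within the caliper and seeded processing order, so "100 different
matchings" is a well-defined, replayable ensemble.

Because the motivating studies' data are access-restricted, the package
ships a synthetic two-cohort generator (`cohort_shift_preset("adni_vs_anm")`)
that emulates the documented demographic shifts between a large ADNI-like
cohort and a smaller AddNeuroMed-like cohort — ≈ 3 years older in the
impaired groups, 4–6 fewer education years, more women, fewer APOE ε4
carriers — with an exponential proportional-hazards survival mechanism
calibrated in closed form so that ≈ 12% of CN+MCI subjects convert within
the 84-month horizon. All analyses, tests and examples run on it.

## Worked example

The numbered scripts under `analysis/` run the whole study on the synthetic
cohorts and write their tables under `results/`:

```sh
Rscript analysis/01_simulate_cohorts.R
Rscript analysis/02_caliper_evaluation.R
Rscript analysis/03_cohort_comparison.R
Rscript analysis/04_risk_model_validation.R
```

`01` prints the generated study conditions:

```
cohort A: 1224 subjects; cohort B: 364 subjects
calibrated baseline hazard: 0.00239 / month
CN+MCI conversion rate within 84 months: 11.8% (target 12%)
MCI  age A 73.1 / B 76.6   education A 15.8 / B 10.1   female A 0.44 / B 0.57
```

`02` reproduces the classical caliper calibration (percent of the initial
single-covariate bias removed by matching) and the sample-size/balance
trade-off on the synthetic MCI groups:

```
 caliper mean_pct_bias_reduction      caliper mean_matched_n mean_balance
     1.0                   67.94          1.0           96.4       0.2467
     0.1                   99.00          0.1           76.3       0.0652
```

(the unmatched balance — mean absolute standardized mean difference over
age, sex, education and APOE ε4 — is 0.76; every caliper improves it, and
tighter calipers trade matched sample size for balance).

`03` is the matched-vs-random comparison. At caliper 1 with 100 matchings
against 100 size-matched random subsamples:

```
 diagnosis unmatched random_mean matched_mean rel_change_pct  p_value
       MCI         4        2.98         2.20         -26.17 1.94e-14
total significant differences: matched 5.5 vs random 6.4 (p = 1.3e-07)
```

i.e. matching removes feature differences beyond what the smaller sample
size alone explains, most clearly in the MCI group where the emulated
shifts are largest.

`04` trains the boosted risk model on cohort A (CN+MCI) and validates it
three ways:

```
C-index: internal 0.650 | external full 0.675 | matched 0.698 (SD 0.012 over 100 matchings)
```

Under the synthetic conditions both cohorts share the same conditional
hazard, so full and matched external performance are close by design; the
vignette (`vignettes/cohort-matching-and-validation.Rmd`) explains which
real-data mechanisms this emulation deliberately leaves out, and the test
suite demonstrates the matched-validation gain under a generator where the
validation cohort lies outside the training support.

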