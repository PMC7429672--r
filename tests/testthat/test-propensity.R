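mk_tab <- function(id, ...) {
  data.frame(subject_id = id, ..., stringsAsFactors = FALSE)
}

test_that("indistinguishable cohorts give null coefficients and scores at 0.5", {
  set.seed(1)
  base <- mk_tab(sprintf("s%03d", 1:200), age = rnorm(200, 70, 7),
                 x = rnorm(200))
  A <- base; B <- base
  B$subject_id <- sub("s", "t", B$subject_id)
  m <- fit_propensity(A, B, c("age", "x"))
  expect_lt(max(abs(coef(m$fit)[-1])), 1e-6)
  expect_equal(unname(m$score_A), rep(0.5, 200), tolerance = 1e-6)
})

test_that("maximum-likelihood fit recovers known logistic coefficients", {
  set.seed(42)
  n <- 20000
  x1 <- rnorm(n); x2 <- rnorm(n)
  member <- rbinom(n, 1, plogis(1.0 * x1 - 0.5 * x2))
  tab <- mk_tab(paste0("s", 1:n), x1 = x1, x2 = x2)
  m <- fit_propensity(tab[member == 0, ], tab[member == 1, ], c("x1", "x2"))
  est <- coef(m$fit)
  expect_lt(abs(est[["x1"]] - 1.0), 0.1)
  expect_lt(abs(est[["x2"]] - (-0.5)), 0.1)
  expect_lt(abs(est[["(Intercept)"]]), 0.1)
})

test_that("a feature present in only one cohort raises a separation error", {
  set.seed(2)
  A <- mk_tab(paste0("a", 1:50), flag = rep("0", 50), age = rnorm(50, 70))
  B <- mk_tab(paste0("b", 1:50), flag = rep("1", 50), age = rnorm(50, 70))
  expect_error(fit_propensity(A, B, c("age", "flag")), "flag")
  # continuous non-overlap is also named
  A$z <- runif(50, 0, 1); B$z <- runif(50, 2, 3)
  expect_error(fit_propensity(A, B, c("age", "z")), "z")
})

test_that("complete-case restriction applies to matching features only", {
  set.seed(3)
  A <- mk_tab(paste0("a", 1:100), age = rnorm(100, 70), x = rnorm(100))
  B <- mk_tab(paste0("b", 1:100), age = rnorm(100, 71), x = rnorm(100))
  A$age[1:10] <- NA
  m <- fit_propensity(A, B, "age")
  expect_length(m$score_A, 90)
  A$age <- NA_real_
  expect_error(fit_propensity(A, B, "age"), "complete cases")
})

test_that("caliper bound and no-replacement invariants hold on every result", {
  set.seed(4)
  sA <- setNames(runif(60, 0.2, 0.8), paste0("a", 1:60))
  sB <- setNames(runif(40, 0.2, 0.8), paste0("b", 1:40))
  for (cf in c(0.1, 0.5, 1.5)) {
    res <- caliper_match_scores(sA, sB, caliper_fraction = cf, seed = 99)
    expect_true(all(abs(res$pairs$score_A - res$pairs$score_B) <=
                      cf * res$score_sd + 1e-12))
    expect_false(anyDuplicated(res$pairs$id_A) > 0)
    expect_false(anyDuplicated(res$pairs$id_B) > 0)
    # pairs and discards partition both cohorts
    expect_setequal(c(res$pairs$id_A, res$discarded_A), names(sA))
    expect_setequal(c(res$pairs$id_B, res$discarded_B), names(sB))
  }
})

test_that("hand-computed caliper examples behave as derived", {
  # single identical score: one pair regardless of caliper
  r <- caliper_match_scores(c(a = 0.5), c(b = 0.5), score_sd = 0.1,
                            caliper_fraction = 0.01, seed = 1)
  expect_equal(nrow(r$pairs), 1)
  expect_length(r$discarded_A, 0)
  # scores 0.1 vs 0.9: pooled sample SD 0.566, caliper 0.2 -> threshold
  # 0.113 < gap 0.8, so nothing matches
  r <- caliper_match_scores(c(a = 0.1), c(b = 0.9), caliper_fraction = 0.2,
                            seed = 1)
  expect_equal(r$score_sd, sd(c(0.1, 0.9)))
  expect_equal(nrow(r$pairs), 0)
  expect_identical(r$discarded_A, "a")
  expect_identical(r$discarded_B, "b")
  expect_error(caliper_match_scores(c(a = 0.5), c(b = 0.5),
                                    caliper_fraction = 0), "caliper")
})

test_that("random selection within the caliper is uniform over candidates", {
  freq <- match_pair_frequency(score_A = 0.50, score_B = c(0.49, 0.51),
                               caliper_fraction = 50, n_seeds = 1000)
  expect_lt(abs(freq[1, 1] - 0.5), 0.05)
  expect_lt(abs(freq[1, 2] - 0.5), 0.05)
})

test_that("sequential matching frequencies agree with exhaustive enumeration", {
  # 3 reference vs 3 pool subjects with asymmetric overlap: the exact
  # pair distribution is enumerable over all orders and choices
  sA <- c(0.30, 0.50, 0.70)
  sB <- c(0.35, 0.55, 0.90)
  thr <- 0.12
  P <- match_pair_distribution(sA, sB, thr)
  n_seeds <- 4000
  F <- match_pair_frequency(sA, sB, caliper_fraction = 1, n_seeds = n_seeds,
                            score_sd = thr)
  for (i in 1:3) for (j in 1:3) {
    se <- sqrt(max(P[i, j] * (1 - P[i, j]), 1e-6) / n_seeds)
    expect_lt(abs(F[i, j] - P[i, j]), 4 * se + 0.005)
  }
})

test_that("nearest-within-caliper picks the minimal score distance", {
  sA <- c(a = 0.50)
  sB <- c(b1 = 0.44, b2 = 0.52, b3 = 0.58)
  hits <- replicate(50, {
    r <- caliper_match_scores(sA, sB, score_sd = 0.1, caliper_fraction = 1,
                              rule = "nearest_within_caliper",
                              seed = sample.int(1e6, 1))
    r$pairs$id_B
  })
  expect_true(all(hits == "b2"))
})

test_that("percent bias reduction matches its defining identities", {
  # matching that retains everything changes nothing: 0%
  vA <- setNames(c(1, 3), c("a1", "a2"))
  vB <- setNames(c(2, 6), c("b1", "b2"))
  res_all <- caliper_match_scores(setNames(c(0.5, 0.5), names(vA)),
                                  setNames(c(0.5, 0.5), names(vB)),
                                  score_sd = 0.1, caliper_fraction = 10, seed = 1)
  expect_equal(nrow(res_all$pairs), 2)
  expect_equal(percent_bias_reduction(vA, vB, res_all), 0)
  # matched means exactly equal: 100%
  res <- structure(list(pairs = data.frame(id_A = c("a1", "a2"),
                                           id_B = c("b2", "b1"))),
                   class = "match_result")
  vB2 <- setNames(c(3, 1, 5), c("b1", "b2", "b3"))
  expect_equal(percent_bias_reduction(vA, vB2, res), 100)
  # zero initial difference is undefined
  expect_error(percent_bias_reduction(vA, setNames(c(1, 3), c("b1", "b2")),
                                      res_all), "zero")
})

test_that("matching strictly improves covariate balance on the shift preset", {
  spec <- cohort_shift_preset("adni_vs_anm", calibrate_rate = NULL)
  co <- generate_paired_cohorts(spec, seed = 21)
  mf <- c("age", "sex", "education_years", "apoe4")
  A <- complete_cases(co$A[co$A$diagnosis == "MCI", ], mf)
  B <- complete_cases(co$B[co$B$diagnosis == "MCI", ], mf)
  model <- fit_propensity(A, B, mf)
  pre <- balance_summary(A, B, mf)
  improved <- vapply(1:100, function(s) {
    res <- caliper_match(model, caliper_fraction = 1, seed = s)
    balance_summary(A, B, mf, res) < pre
  }, logical(1))
  expect_gte(sum(improved), 95)
})

test_that("caliper sweep shrinks matched n and improves balance as the caliper tightens", {
  spec <- cohort_shift_preset("adni_vs_anm", calibrate_rate = NULL)
  co <- generate_paired_cohorts(spec, seed = 31)
  mf <- c("age", "sex", "education_years", "apoe4")
  A <- co$A[co$A$diagnosis == "MCI", ]; B <- co$B[co$B$diagnosis == "MCI", ]
  sw <- caliper_sweep(A, B, mf, n_repeats = 20, seed = 5)
  expect_equal(sw$caliper, c(1.5, 1.3, 1, 0.7, 0.5, 0.3, 0.1))
  # matched n non-increasing as the caliper shrinks
  expect_true(all(diff(sw$mean_matched_n) <= 0))
  # balance improves from the widest to the tightest caliper, and every
  # post-match balance beats the unmatched value
  expect_lt(sw$mean_balance[7], sw$mean_balance[1])
  expect_true(all(sw$mean_balance < sw$balance_unmatched))
  # degenerate sweep equals a single matching plus balance computation
  one <- caliper_sweep(A, B, mf, calipers = 1, n_repeats = 1, seed = 7)
  expect_equal(nrow(one), 1)
})

test_that("logit-scale caliper option changes the matching scale coherently", {
  set.seed(8)
  A <- mk_tab(paste0("a", 1:150), age = rnorm(150, 70, 5))
  B <- mk_tab(paste0("b", 1:150), age = rnorm(150, 72, 5))
  m <- fit_propensity(A, B, "age")
  r_raw <- caliper_match(m, caliper_fraction = 0.5, seed = 3, caliper_scale = "raw")
  r_log <- caliper_match(m, caliper_fraction = 0.5, seed = 3, caliper_scale = "logit")
  lo <- qlogis(unname(m$score_A[r_log$pairs$id_A]))
  lb <- qlogis(unname(m$score_B[r_log$pairs$id_B]))
  expect_true(all(abs(lo - lb) <= 0.5 * m$score_sd_logit + 1e-12))
  expect_gt(nrow(r_raw$pairs), 0)
})
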