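test_that("Welch interval matches the hand-computed example", {
  # x = {10,12,14,16}, y = {1,2,3,4}: d = 10.5, se = sqrt(20/3/4 + 5/3/4)
  x <- c(10, 12, 14, 16); y <- c(1, 2, 3, 4)
  se <- sqrt(var(x) / 4 + var(y) / 4)
  expect_equal(se, 1.443376, tolerance = 1e-6)
  df <- se^4 / ((var(x) / 4)^2 / 3 + (var(y) / 4)^2 / 3)
  expect_equal(df, 4.411765, tolerance = 1e-6)
  ci <- mean_diff_ci(x, y, 0.95)
  expect_equal((ci$lower + ci$upper) / 2, 10.5)
  expect_equal(ci$upper - ci$lower, 2 * qt(0.975, df) * se, tolerance = 1e-10)
  expect_true(ci$significant)

  # identical samples: centred at zero, not significant
  ci0 <- mean_diff_ci(c(1, 2, 3), c(1, 2, 3), 0.95)
  expect_equal((ci0$lower + ci0$upper) / 2, 0)
  expect_false(ci0$significant)

  expect_error(mean_diff_ci(1, c(1, 2)), "2 non-missing")
})

test_that("interval width is monotone in the confidence level", {
  set.seed(1)
  x <- rnorm(30); y <- rnorm(25, 0.3)
  narrow <- mean_diff_ci(x, y, 0.95)
  wide <- mean_diff_ci(x, y, 0.99975)
  expect_lt(wide$lower, narrow$lower)
  expect_gt(wide$upper, narrow$upper)
})

test_that("Wald proportion interval matches the hand-computed example", {
  # 50/100 vs 25/100: d = 0.25, half-width 1.96 * 0.066144 = 0.1296
  ci <- proportion_diff_ci(50, 100, 25, 100, 0.95)
  se <- sqrt(0.5 * 0.5 / 100 + 0.25 * 0.75 / 100)
  expect_equal(se, 0.0661438, tolerance = 1e-6)
  expect_equal(ci$lower, 0.25 - qnorm(0.975) * se, tolerance = 1e-10)
  expect_equal(ci$upper, 0.25 + qnorm(0.975) * se, tolerance = 1e-10)
  expect_true(ci$significant)

  eq <- proportion_diff_ci(20, 50, 40, 100, 0.95)
  expect_equal((eq$lower + eq$upper) / 2, 0)
  expect_false(eq$significant)

  # zero-variance degenerate case: zero-width interval at 0
  z <- proportion_diff_ci(0, 10, 0, 10, 0.95)
  expect_equal(z$lower, 0); expect_equal(z$upper, 0)
  expect_false(z$significant)
  expect_error(proportion_diff_ci(1, 0, 1, 10), "sample sizes")
})

test_that("interval significance is dual to the Welch test p-value", {
  set.seed(7)
  m <- 12
  for (r in 1:40) {
    x <- rnorm(20, 0, 1); y <- rnorm(25, rnorm(1, 0, 0.5), 1.3)
    ci <- mean_diff_ci(x, y, 1 - 0.05 / m)
    p <- t.test(x, y)$p.value
    expect_identical(ci$significant, p < 0.05 / m)
  }
})

test_that("identical tables yield zero significant differences", {
  set.seed(2)
  tab <- data.frame(a = rnorm(50), b = rnorm(50),
                    g = sample(c("x", "y"), 50, TRUE))
  dict <- data_dictionary(c("a", "b", "g"),
                          c("continuous", "continuous", "categorical"),
                          list(NULL, NULL, c("x", "y")))
  rep <- count_significant_differences(tab, tab, dict, alpha = 0.05)
  expect_equal(rep$count, 0)
  expect_equal(rep$m, 4)  # 2 continuous + 2 categories
  expect_error(count_significant_differences(tab, tab, dict[0, ], 0.05), "empty")
})

test_that("shifted features are detected and null features stay quiet", {
  # 10 features shifted by 2 pooled SDs + 190 null features, n = 500/cohort
  n <- 500; runs <- 20
  dict <- data_dictionary(sprintf("f%03d", 1:200), rep("continuous", 200))
  hits <- vapply(1:runs, function(r) {
    set.seed(1000 + r)
    A <- as.data.frame(matrix(rnorm(n * 200), n))
    B <- as.data.frame(matrix(rnorm(n * 200), n))
    names(A) <- names(B) <- dict$name
    B[, 1:10] <- B[, 1:10] + 2
    count_significant_differences(A, B, dict, alpha = 0.05)$count
  }, numeric(1))
  expect_gte(mean(hits == 10), 0.95)

  # one overwhelming shift is always found
  set.seed(3)
  A1 <- data.frame(f = rnorm(100)); B1 <- data.frame(f = rnorm(100) + 5)
  d1 <- data_dictionary("f", "continuous")
  expect_equal(count_significant_differences(A1, B1, d1, 0.05)$count, 1)
})

test_that("random subsample counts are seeded, sized and degenerate-correct", {
  set.seed(4)
  A <- data.frame(subject_id = paste0("a", 1:80), f = rnorm(80), g = rnorm(80))
  B <- data.frame(subject_id = paste0("b", 1:60), f = rnorm(60, 1), g = rnorm(60))
  dict <- data_dictionary(c("f", "g"), c("continuous", "continuous"))
  c1 <- random_subsample_counts(A, B, dict, 40, 30, n_reps = 5, seed = 9)
  c2 <- random_subsample_counts(A, B, dict, 40, 30, n_reps = 5, seed = 9)
  expect_identical(c1, c2)
  expect_length(c1, 5)
  # drawing the full cohorts without replacement is the identity
  full <- count_significant_differences(A, B, dict, 0.05)$count
  cf <- random_subsample_counts(A, B, dict, 80, 60, n_reps = 3, seed = 2)
  expect_true(all(cf == full))
  expect_error(random_subsample_counts(A, B, dict, 81, 60, n_reps = 1, seed = 1),
               "exceeds")
})

test_that("rank-sum comparison of matched vs random counts is exact for small lists", {
  # complete separation of 3 vs 3: exactly 1 of the 20 rank assignments
  expect_equal(matched_vs_random_test(c(1, 2, 3), c(10, 11, 12)), 1 / 20)
  # identical lists: no evidence of a downward shift
  p_same <- matched_vs_random_test(c(5, 6, 7, 8), c(5, 6, 7, 8))
  expect_gt(p_same, 0.3)
  expect_error(matched_vs_random_test(integer(0), c(1)), "empty")
})

test_that("stochastically lower matched counts give p < 0.001", {
  set.seed(11)
  ok <- vapply(1:20, function(r) {
    matched <- rpois(100, 20)
    random <- rpois(100, 66)
    matched_vs_random_test(matched, random) < 0.001
  }, logical(1))
  expect_gte(mean(ok), 0.99)
})
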