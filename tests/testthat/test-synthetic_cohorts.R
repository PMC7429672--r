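test_that("spec invariants are enforced", {
  expect_error(feature_spec("p", "categorical",
                            params = list(A = c(0.5, 0.4), B = c(0.5, 0.5)),
                            categories = c("a", "b")),
               "sum to 1")
  expect_error(feature_spec("x", "continuous",
                            params = list(A = c(0, 0), B = c(0, 1))),
               "standard deviation")
  expect_error(simple_spec(nA = c(CN = 0, MCI = 0, DEM = 0)), "zero total")
  expect_error(shift_spec(list(), n = list(A = c(CN = 1), B = c(CN = 1)),
                          horizon = -1), "horizon")
  expect_error(shift_spec(list(), n = list(A = c(CN = 1), B = c(CN = 1)),
                          baseline_hazard = -0.1), "baseline hazard")
})

test_that("identical seed reproduces identical cohorts bit for bit", {
  spec <- simple_spec(baseline_hazard = 0.01, age_loading = 0.3)
  a <- generate_paired_cohorts(spec, seed = 11)
  b <- generate_paired_cohorts(spec, seed = 11)
  expect_identical(a, b)
  c <- generate_paired_cohorts(spec, seed = 12)
  expect_false(identical(a$A$age, c$A$age))
})

test_that("identical generators leave only sampling noise between cohorts", {
  spec <- simple_spec(nA = c(CN = 500, MCI = 0, DEM = 0),
                      nB = c(CN = 500, MCI = 0, DEM = 0))
  co <- generate_paired_cohorts(spec, seed = 1)
  for (f in c("age", "x")) {
    smd <- abs(mean(co$A[[f]]) - mean(co$B[[f]])) /
      sqrt((var(co$A[[f]]) + var(co$B[[f]])) / 2)
    expect_lt(smd, 0.2)
  }
})

test_that("a +3-year age shift in cohort B is recovered at n = 2000/group", {
  spec <- simple_spec(nA = c(CN = 0, MCI = 2000, DEM = 0),
                      nB = c(CN = 0, MCI = 2000, DEM = 0),
                      age_shift_B = 3)
  co <- generate_paired_cohorts(spec, seed = 5)
  diff <- mean(co$B$age) - mean(co$A$age)
  mc_se <- sqrt(49 / 2000 + 49 / 2000)
  expect_lt(abs(diff - 3), 3 * mc_se)
})

test_that("sample moments converge to spec parameters (law of large numbers)", {
  spec <- shift_spec(
    features = list(
      feature_spec("y", "continuous", params = list(A = c(2, 3), B = c(2, 3))),
      feature_spec("g", "categorical",
                   params = list(A = c(0.2, 0.5, 0.3), B = c(0.2, 0.5, 0.3)),
                   categories = c("u", "v", "w"))),
    n = list(A = c(CN = 20000, MCI = 0, DEM = 0), B = c(CN = 100, MCI = 0, DEM = 0)),
    baseline_hazard = 0)
  co <- generate_paired_cohorts(spec, seed = 3)
  expect_lt(abs(mean(co$A$y) - 2), 3 * 3 / sqrt(20000))
  for (k in seq_along(c(u = 0.2, v = 0.5, w = 0.3))) {
    p <- c(u = 0.2, v = 0.5, w = 0.3)[k]
    phat <- mean(co$A$g == names(p))
    expect_lt(abs(phat - p), 3 * sqrt(p * (1 - p) / 20000))
  }
})

test_that("survival outcomes respect censoring consistency and hazard limits", {
  spec0 <- simple_spec(baseline_hazard = 0)
  co <- generate_paired_cohorts(spec0, seed = 2)
  expect_true(all(co$A$event == 0))
  expect_true(all(co$A$time == spec0$horizon))

  spec_hi <- simple_spec(baseline_hazard = 10)
  co <- generate_paired_cohorts(spec_hi, seed = 2)
  expect_true(all(co$A$event == 1))
  expect_true(all(co$A$time < 1))  # hazard 10/month: events almost immediately

  spec_mid <- simple_spec(baseline_hazard = 0.005, age_loading = 0.5)
  co <- generate_paired_cohorts(spec_mid, seed = 2)
  tab <- rbind(co$A, co$B)
  expect_true(all((tab$event == 0) == (tab$time == spec_mid$horizon)))
  expect_true(all(tab$time > 0 & tab$time <= spec_mid$horizon))
})

test_that("closed-form calibration hits the target CN+MCI conversion rate", {
  # scale the preset to ~2000 CN+MCI subjects, keeping group proportions
  spec <- cohort_shift_preset("adni_vs_anm",
                              n = list(A = c(CN = 536, MCI = 1035, DEM = 510),
                                       B = c(CN = 187, MCI = 228, DEM = 204)))
  co <- generate_paired_cohorts(spec, seed = 9)
  tab <- rbind(co$A, co$B)
  tab <- tab[tab$diagnosis %in% c("CN", "MCI"), ]
  n <- nrow(tab)
  rate <- mean(tab$event)
  expect_lt(abs(rate - 0.12), 3 * sqrt(0.12 * 0.88 / n))
})

test_that("missingness is injected at the configured rate and filtered", {
  spec <- simple_spec(nA = c(CN = 2000, MCI = 0, DEM = 0),
                      nB = c(CN = 50, MCI = 0, DEM = 0), x_missing = 0.2)
  co <- generate_paired_cohorts(spec, seed = 4)
  fr <- mean(is.na(co$A$x))
  expect_lt(abs(fr - 0.2), 3 * sqrt(0.2 * 0.8 / 2000))
  cc <- complete_cases(co$A, c("age", "x"))
  expect_false(anyNA(cc$x))
  expect_equal(nrow(cc), sum(!is.na(co$A$x)))
})

test_that("cohort tables round-trip through CSV and the dictionary through JSON", {
  spec <- cohort_shift_preset("adni_vs_anm",
                              n = list(A = c(CN = 20, MCI = 20, DEM = 10),
                                       B = c(CN = 10, MCI = 10, DEM = 10)),
                              calibrate_rate = NULL)
  co <- generate_paired_cohorts(spec, seed = 1)
  dict <- spec_dictionary(spec)
  tf <- tempfile(fileext = ".csv"); jf <- tempfile(fileext = ".json")
  write_cohort_csv(co$A, tf)
  back <- read_cohort_csv(tf)
  expect_equal(back$age, co$A$age, tolerance = 1e-12)
  expect_identical(as.character(back$apoe4), co$A$apoe4)
  write_dictionary(dict, jf)
  d2 <- read_dictionary(jf)
  expect_identical(d2$name, dict$name)
  expect_identical(d2$kind, dict$kind)
  expect_identical(d2$categories[[which(d2$name == "apoe4")]], c("0", "1", "2"))
})
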