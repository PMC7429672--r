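#' @title Study-level pipelines
#' @description Orchestrates the three analyses end to end: (i) per-diagnosis
#'   cohort comparison with repeated matchings against a random-subsample
#'   null, (ii) external validation of a risk model on the full eligible
#'   validation cohort, and (iii) matched validation averaged over repeated
#'   matchings.  Everything is replayable from one master seed.
#' @name pipeline
NULL

#' Default pipeline configuration
#'
#' @param matching_features features of the cohort-discriminating model for
#'   the comparison analysis (demographics: age, sex, education, APOE e4).
#' @param validation_matching_features matching features of the matched
#'   validation protocol (demographics plus baseline MMSE, to correct for
#'   differences in cognitive impairment).
#' @param caliper caliper fraction (default 1 SD).
#' @param rule within-caliper selection rule.
#' @param reps repeated matchings / random subsamples for the comparison.
#' @param alpha familywise level of the interval comparisons.
#' @param eligible_diagnoses diagnosis groups eligible for validation
#'   (baseline CN and MCI; dementia cases cannot convert).
#' @param auc_grid monthly AUC(t) horizons (0 retained: undefined there).
#' @param horizon follow-up horizon in months.
#' @return A named list.
#' @export
pipeline_config <- function(matching_features = c("age", "sex", "education_years", "apoe4"),
                            validation_matching_features = c("age", "sex", "education_years", "apoe4", "mmse"),
                            caliper = 1, rule = "random_within_caliper",
                            reps = 100, alpha = 0.05,
                            eligible_diagnoses = c("CN", "MCI"),
                            auc_grid = 0:84, horizon = 84) {
  list(matching_features = matching_features,
       validation_matching_features = validation_matching_features,
       caliper = caliper, rule = rule, reps = reps, alpha = alpha,
       eligible_diagnoses = eligible_diagnoses, auc_grid = auc_grid,
       horizon = horizon)
}

#' Per-diagnosis cohort comparison with matched and random-subsample counts
#'
#' For each diagnosis group separately: (1) the full-group comparison of
#' all dictionary features, (2) `reps` seeded matchings on the matching
#' features followed by a comparison of the matched sub-cohorts, (3)
#' `reps` random subsamples of the same sizes as the corresponding matched
#' sets, compared identically, (4) the one-tailed rank-sum test of matched
#' vs. random counts and the relative change in the mean count.
#'
#' @param A,B cohort tables.
#' @param dictionary comparison feature dictionary.
#' @param config a [pipeline_config()].
#' @param seed master seed.
#' @return Named list (one entry per diagnosis) of lists with
#'   `unmatched_count`, `matched_counts`, `random_counts`, `p_value`,
#'   `relative_change_pct`, `mean_matched_n`.
#' @export
run_cohort_comparison <- function(A, B, dictionary, config = pipeline_config(),
                                  seed = 1L) {
  mf <- config$matching_features
  missing_cols <- setdiff(mf, intersect(names(A), names(B)))
  if (length(missing_cols)) {
    stop("matching feature(s) missing from the cohorts: ",
         paste(missing_cols, collapse = ", "))
  }
  groups <- intersect(DIAGNOSES, intersect(unique(A$diagnosis), unique(B$diagnosis)))
  seeds <- child_seeds(seed, length(groups))
  out <- list()
  for (g in seq_along(groups)) {
    dx <- groups[g]
    Ad <- complete_cases(A[A$diagnosis == dx, , drop = FALSE], mf)
    Bd <- complete_cases(B[B$diagnosis == dx, , drop = FALSE], mf)
    full <- count_significant_differences(Ad, Bd, dictionary, config$alpha)
    model <- fit_propensity(Ad, Bd, mf)
    rep_seeds <- child_seeds(seeds[g], 2 * config$reps + 1)
    matched_counts <- integer(config$reps)
    matched_n <- integer(config$reps)
    for (r in seq_len(config$reps)) {
      res <- caliper_match(model, caliper_fraction = config$caliper,
                           rule = config$rule, seed = rep_seeds[r])
      ia <- match(res$pairs$id_A, Ad$subject_id)
      ib <- match(res$pairs$id_B, Bd$subject_id)
      matched_n[r] <- nrow(res$pairs)
      matched_counts[r] <- count_significant_differences(
        Ad[ia, , drop = FALSE], Bd[ib, , drop = FALSE],
        dictionary, config$alpha)$count
    }
    random_counts <- random_subsample_counts(
      Ad, Bd, dictionary, size_A = matched_n, size_B = matched_n,
      n_reps = config$reps, alpha = config$alpha,
      seed = rep_seeds[2 * config$reps + 1])
    p <- if (config$reps > 1) matched_vs_random_test(matched_counts, random_counts) else NA_real_
    out[[dx]] <- list(
      unmatched_count = full$count,
      unmatched_report = full,
      matched_counts = matched_counts,
      random_counts = random_counts,
      mean_matched_n = mean(matched_n),
      p_value = p,
      relative_change_pct = 100 * (mean(matched_counts) - mean(random_counts)) /
        mean(random_counts))
  }
  out
}

validation_report <- function(mode, c_values, auc_list, n_validated,
                              n_converters, n_excluded = 0, seed = NA) {
  c_values <- c_values[!is.na(c_values)]
  n_m <- length(c_values)
  auc_mat <- do.call(cbind, lapply(auc_list, `[[`, "auc"))
  months <- auc_list[[1]]$month
  auc_mean <- rowMeans(auc_mat, na.rm = TRUE)
  auc_mean[is.nan(auc_mean)] <- NA_real_
  n_def <- rowSums(!is.na(auc_mat))
  auc_se <- if (n_m > 1) {
    se <- apply(auc_mat, 1, stats::sd, na.rm = TRUE) / sqrt(pmax(n_def, 1))
    ifelse(n_def > 1, se, NA_real_)
  } else rep(NA_real_, length(months))
  structure(list(
    mode = mode,
    c_index = mean(c_values),
    c_index_sd = if (n_m > 1) stats::sd(c_values) else NA_real_,
    c_values = c_values,
    auc = data.frame(month = months, auc = auc_mean, se = auc_se,
                     n_defined = n_def),
    n_validated = n_validated, n_converters = n_converters,
    n_matchings = n_m, n_excluded = n_excluded, seed = seed),
    class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("validation [%s]: C-index %.3f%s over %d evaluation(s); n = %.1f (%.1f converters)\n",
              x$mode, x$c_index,
              if (!is.na(x$c_index_sd)) sprintf(" (SD %.3f)", x$c_index_sd) else "",
              x$n_matchings, mean(x$n_validated), mean(x$n_converters)))
  invisible(x)
}

#' External validation on the full eligible validation cohort
#'
#' Scores every baseline-CN/MCI subject of the validation cohort that is
#' complete for the model's features and evaluates Harrell's C and the
#' monthly AUC(t) curve.
#'
#' @param model a fitted `risk_model`.
#' @param B validation cohort table.
#' @param config a [pipeline_config()].
#' @return A `validation_report` (mode `"external_full"`).
#' @export
run_external_validation <- function(model, B, config = pipeline_config()) {
  elig <- B[B$diagnosis %in% config$eligible_diagnoses, , drop = FALSE]
  elig <- complete_cases(elig, c(model$features, "time", "event"))
  if (nrow(elig) == 0) stop("no eligible validation subjects")
  sc <- predict_risk(model, elig)
  curve <- td_auc_curve(sc, elig$time, elig$event, config$auc_grid)
  validation_report("external_full",
                    c_values = harrell_c(sc, elig$time, elig$event),
                    auc_list = list(curve),
                    n_validated = nrow(elig),
                    n_converters = sum(elig$event))
}

#' Matched external validation averaged over repeated matchings
#'
#' The matching features are the demographic set plus baseline MMSE; no
#' stratification by baseline diagnosis is performed before matching.  Per
#' matching, the validation set is the B-side matched partners restricted
#' to eligible (CN/MCI, feature-complete) subjects; Harrell's C and AUC(t)
#' are computed per matching and averaged.  Matchings whose validation set
#' yields an undefined C (e.g. no converters) are excluded from the mean
#' and counted.
#'
#' @param model a fitted `risk_model`.
#' @param A training-side cohort (defines the matching reference).
#' @param B validation cohort.
#' @param config a [pipeline_config()].
#' @param n_matchings number of repeated matchings (study protocol: 100).
#' @param seed master seed.
#' @return A `validation_report` (mode `"external_matched"`).
#' @export
run_matched_validation <- function(model, A, B, config = pipeline_config(),
                                   n_matchings = 100, seed = 1L) {
  mf <- config$validation_matching_features
  pm <- fit_propensity(A, B, mf)
  Bc <- complete_cases(B, mf)
  seeds <- child_seeds(seed, n_matchings)
  c_vals <- rep(NA_real_, n_matchings)
  auc_list <- list()
  n_val <- numeric(n_matchings); n_conv <- numeric(n_matchings)
  n_excluded <- 0L
  for (r in seq_len(n_matchings)) {
    res <- caliper_match(pm, caliper_fraction = config$caliper,
                         rule = config$rule, seed = seeds[r])
    sel <- Bc[Bc$subject_id %in% res$pairs$id_B, , drop = FALSE]
    sel <- sel[sel$diagnosis %in% config$eligible_diagnoses, , drop = FALSE]
    sel <- complete_cases(sel, c(model$features, "time", "event"))
    n_val[r] <- nrow(sel); n_conv[r] <- sum(sel$event)
    cr <- tryCatch({
      sc <- predict_risk(model, sel)
      list(c = harrell_c(sc, sel$time, sel$event),
           curve = td_auc_curve(sc, sel$time, sel$event, config$auc_grid))
    }, error = function(e) NULL)
    if (is.null(cr)) {
      n_excluded <- n_excluded + 1L
      message("matching ", r, ": concordance undefined; excluded from the mean")
      next
    }
    c_vals[r] <- cr$c
    auc_list[[length(auc_list) + 1L]] <- cr$curve
  }
  if (!length(auc_list)) stop("every matching yielded an undefined concordance")
  rep_ <- validation_report("external_matched", c_vals, auc_list,
                            n_validated = mean(n_val),
                            n_converters = mean(n_conv),
                            n_excluded = n_excluded, seed = seed)
  rep_$n_matchings_requested <- n_matchings
  rep_
}

#' Internal cross-validated performance on the training cohort
#'
#' @param A training cohort table.
#' @param features model features.
#' @param config a [pipeline_config()].
#' @param learner,hyper_grid,k,repeats,seed passed to [nested_cv_cindex()].
#' @return A list of class `validation_report`-like with mode
#'   `"internal_cv"` and `c_index`.
#' @export
run_internal_cv <- function(A, features, config = pipeline_config(),
                            learner = "boosted_cox", hyper_grid = NULL,
                            k = 10, repeats = 10, seed = 1L) {
  elig <- A[A$diagnosis %in% config$eligible_diagnoses, , drop = FALSE]
  cv <- nested_cv_cindex(elig, features, learner = learner,
                         hyper_grid = hyper_grid, k = k, repeats = repeats,
                         seed = seed)
  structure(list(mode = "internal_cv", c_index = cv$mean_c,
                 c_index_sd = stats::sd(as.numeric(cv$fold_c), na.rm = TRUE),
                 fold_c = cv$fold_c, n_validated = nrow(elig),
                 n_converters = sum(elig$event), n_matchings = 1L,
                 seed = seed),
            class = "validation_report")
}

#' Serialize a validation report to JSON (+ AUC curve CSV)
#' @param report a `validation_report`.
#' @param json_path output JSON path; `csv_path` optional AUC CSV path.
#' @export
write_validation_report <- function(report, json_path, csv_path = NULL) {
  obj <- report[c("mode", "c_index", "c_index_sd", "n_validated",
                  "n_converters", "n_matchings", "n_excluded", "seed")]
  obj <- obj[!vapply(obj, is.null, logical(1))]
  jsonlite::write_json(obj, json_path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  if (!is.null(csv_path) && !is.null(report$auc)) write_auc_csv(report$auc, csv_path)
  invisible(json_path)
}
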