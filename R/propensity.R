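#' @title Propensity score estimation and caliper matching
#' @description Fits the logistic model that discriminates between two
#'   cohorts and performs greedy 1:1 matching under a caliper expressed as
#'   a fraction of the propensity score's standard deviation.  Matching is
#'   without replacement; partners inside the caliper are chosen uniformly
#'   at random (default) or by nearest score distance; subjects without a
#'   partner are discarded.
#' @name propensity
NULL

#' Fit the cohort-discriminating logistic model
#'
#' Membership (cohort B = 1 vs A = 0) is regressed on the matching
#' features by unpenalized maximum likelihood.  Only subjects complete
#' with respect to the matching features are used.  The returned model
#' carries the pooled standard deviation of the fitted scores over both
#' cohorts, which defines the caliper scale.
#'
#' @param A,B cohort tables.
#' @param matching_features character vector of feature column names.
#' @param dictionary optional data dictionary; character columns are
#'   treated as categorical either way.
#' @return A `propensity_model` object with elements `fit` (the glm),
#'   `matching_features`, `score_A`, `score_B` (named by subject id),
#'   `score_sd` (pooled, raw scale), `score_sd_logit`, `ids_A`, `ids_B`.
#' @export
fit_propensity <- function(A, B, matching_features, dictionary = NULL) {
  A <- complete_cases(A, matching_features)
  B <- complete_cases(B, matching_features)
  if (nrow(A) == 0 || nrow(B) == 0) {
    stop("no complete cases with respect to the matching features in cohort ",
         if (nrow(A) == 0) "A" else "B")
  }
  check_separation(A, B, matching_features)
  dat <- rbind(
    cbind(A[, matching_features, drop = FALSE], .membership = 0),
    cbind(B[, matching_features, drop = FALSE], .membership = 1))
  for (f in matching_features) {
    if (!is.numeric(dat[[f]])) dat[[f]] <- factor(dat[[f]])
  }
  form <- stats::as.formula(paste(".membership ~",
                                  paste(sprintf("`%s`", matching_features), collapse = " + ")))
  fit <- suppressWarnings(stats::glm(form, data = dat, family = stats::binomial()))
  if (!fit$converged || any(abs(stats::coef(fit)[-1]) > 15, na.rm = TRUE)) {
    stop("propensity fit did not converge; possible separation in the matching features")
  }
  p <- stats::fitted(fit)
  nA <- nrow(A)
  score_A <- stats::setNames(p[seq_len(nA)], A$subject_id)
  score_B <- stats::setNames(p[nA + seq_len(nrow(B))], B$subject_id)
  structure(list(fit = fit, matching_features = matching_features,
                 score_A = score_A, score_B = score_B,
                 score_sd = stats::sd(p),
                 score_sd_logit = stats::sd(stats::qlogis(p)),
                 ids_A = A$subject_id, ids_B = B$subject_id),
            class = "propensity_model")
}

# Error (naming the feature) when a matching feature separates the cohorts:
# continuous ranges that do not overlap, or a category observed in exactly
# one cohort.
check_separation <- function(A, B, matching_features) {
  for (f in matching_features) {
    a <- A[[f]]; b <- B[[f]]
    if (is.numeric(a)) {
      if (max(a) < min(b) || max(b) < min(a)) {
        stop("matching feature '", f, "' perfectly separates the cohorts")
      }
    } else {
      only <- union(setdiff(unique(a), unique(b)), setdiff(unique(b), unique(a)))
      if (length(only)) {
        stop("matching feature '", f, "' separates the cohorts: category ",
             paste(sprintf("'%s'", only), collapse = ", "),
             " observed in only one cohort")
      }
    }
  }
  invisible(NULL)
}

#' Predict propensity scores for new subjects
#' @param model a `propensity_model`.
#' @param table a cohort table containing the matching features.
#' @return Numeric scores in (0, 1), named by subject id.
#' @export
predict_propensity <- function(model, table) {
  tab <- complete_cases(table, model$matching_features)
  stats::setNames(
    as.numeric(stats::predict(model$fit, newdata = tab, type = "response")),
    tab$subject_id)
}

#' Greedy 1:1 caliper matching on precomputed scores
#'
#' Low-level engine behind [caliper_match()], also usable with any scalar
#' matching variable (e.g. a single covariate).  Reference-side subjects
#' are processed in a seeded uniform random order; each is matched to an
#' unmatched partner whose score differs by at most
#' `caliper_fraction * score_sd`, chosen uniformly at random within the
#' caliper (default) or as the nearest score (ties broken at random).
#'
#' @param score_A,score_B numeric score vectors named by subject id.
#' @param score_sd the score standard deviation defining the caliper scale
#'   (default: pooled sample SD over both score vectors).
#' @param caliper_fraction positive caliper width in SD units.
#' @param rule `"random_within_caliper"` or `"nearest_within_caliper"`.
#' @param seed integer seed (drives the processing order and the
#'   within-caliper selection).
#' @param reference which side's subjects seek partners (default `"A"`).
#' @return A `match_result`: `pairs` (data.frame `id_A`, `id_B`,
#'   `score_A`, `score_B`), `discarded_A`, `discarded_B`, `caliper_fraction`,
#'   `rule`, `seed`, `score_sd`.
#' @export
caliper_match_scores <- function(score_A, score_B, score_sd = NULL,
                                 caliper_fraction,
                                 rule = c("random_within_caliper",
                                          "nearest_within_caliper"),
                                 seed, reference = c("A", "B")) {
  rule <- match.arg(rule)
  reference <- match.arg(reference)
  if (caliper_fraction <= 0) stop("caliper_fraction must be > 0")
  if (length(score_A) == 0 || length(score_B) == 0) stop("empty cohort")
  if (is.null(names(score_A))) names(score_A) <- paste0("A", seq_along(score_A))
  if (is.null(names(score_B))) names(score_B) <- paste0("B", seq_along(score_B))
  if (is.null(score_sd)) score_sd <- stats::sd(c(score_A, score_B))
  threshold <- caliper_fraction * score_sd

  ref <- if (reference == "A") score_A else score_B
  pool <- if (reference == "A") score_B else score_A
  ord_pool <- order(pool)
  pool_sorted <- pool[ord_pool]
  used <- rep(FALSE, length(pool))

  sel_ref <- integer(0); sel_pool <- integer(0)
  with_seed(seed, {
    for (i in sample.int(length(ref))) {
      lo <- findInterval(ref[i] - threshold, pool_sorted, left.open = TRUE) + 1L
      hi <- findInterval(ref[i] + threshold, pool_sorted)
      if (hi < lo) next
      cand <- (lo:hi)[!used[lo:hi]]
      if (!length(cand)) next
      j <- if (rule == "random_within_caliper" || length(cand) == 1L) {
        cand[sample.int(length(cand), 1L)]
      } else {
        d <- abs(pool_sorted[cand] - ref[i])
        best <- cand[d == min(d)]
        best[sample.int(length(best), 1L)]
      }
      used[j] <- TRUE
      sel_ref <- c(sel_ref, i)
      sel_pool <- c(sel_pool, ord_pool[j])
    }
  })
  if (reference == "A") { ia <- sel_ref; ib <- sel_pool } else { ia <- sel_pool; ib <- sel_ref }
  pairs <- data.frame(id_A = names(score_A)[ia], id_B = names(score_B)[ib],
                      score_A = unname(score_A[ia]), score_B = unname(score_B[ib]),
                      stringsAsFactors = FALSE)
  structure(list(pairs = pairs,
                 discarded_A = setdiff(names(score_A), pairs$id_A),
                 discarded_B = setdiff(names(score_B), pairs$id_B),
                 caliper_fraction = caliper_fraction, rule = rule,
                 seed = seed, score_sd = score_sd, reference = reference),
            class = "match_result")
}

#' Caliper-based 1:1 propensity score matching
#'
#' @param model a `propensity_model` from [fit_propensity()].
#' @param A,B the cohort tables the model was fitted on (used only for
#'   id consistency checks; scores are taken from the model).
#' @param caliper_fraction positive caliper width, in units of the score's
#'   standard deviation.
#' @param rule partner selection rule within the caliper.
#' @param seed integer seed.
#' @param caliper_scale `"raw"` (pooled SD of the scores; default) or
#'   `"logit"` (SD of the logit-transformed scores — in that case the
#'   matching distance is on the logit scale too).
#' @param reference which cohort's subjects seek partners.
#' @return A `match_result`; see [caliper_match_scores()].
#' @export
caliper_match <- function(model, A = NULL, B = NULL, caliper_fraction = 1,
                          rule = c("random_within_caliper",
                                   "nearest_within_caliper"),
                          seed = 1L, caliper_scale = c("raw", "logit"),
                          reference = c("A", "B")) {
  rule <- match.arg(rule)
  caliper_scale <- match.arg(caliper_scale)
  reference <- match.arg(reference)
  if (caliper_scale == "raw") {
    caliper_match_scores(model$score_A, model$score_B,
                         score_sd = model$score_sd,
                         caliper_fraction = caliper_fraction,
                         rule = rule, seed = seed, reference = reference)
  } else {
    res <- caliper_match_scores(stats::qlogis(model$score_A),
                                stats::qlogis(model$score_B),
                                score_sd = model$score_sd_logit,
                                caliper_fraction = caliper_fraction,
                                rule = rule, seed = seed, reference = reference)
    # report scores on the probability scale
    res$pairs$score_A <- unname(model$score_A[res$pairs$id_A])
    res$pairs$score_B <- unname(model$score_B[res$pairs$id_B])
    res
  }
}

#' Percent reduction of the initial covariate bias achieved by matching
#'
#' `100 * (1 - |mean difference over matched subjects| /
#' |mean difference over all subjects|)`: 100 means the matched means are
#' equal, 0 means matching changed nothing (e.g. everything matched).
#'
#' @param values_A,values_B numeric covariate vectors named by subject id
#'   (all subjects that entered the matching).
#' @param result a `match_result`.
#' @return Percent bias reduction (can be negative if matching worsened
#'   the imbalance).
#' @export
percent_bias_reduction <- function(values_A, values_B, result) {
  if (nrow(result$pairs) == 0) stop("no matched pairs")
  initial <- mean(values_A) - mean(values_B)
  if (initial == 0) stop("initial mean difference is zero; bias reduction undefined")
  matched <- mean(values_A[result$pairs$id_A]) - mean(values_B[result$pairs$id_B])
  100 * (1 - abs(matched) / abs(initial))
}

# Standardized mean difference of one feature between matched halves,
# using the pre-match pooled SD as denominator (so values are comparable
# before/after matching).  Categorical features are expanded to category
# indicators and averaged.
feature_smd <- function(xA, xB, idx_A = NULL, idx_B = NULL) {
  code_cols <- function(x) {
    if (is.numeric(x)) return(matrix(x, ncol = 1))
    lev <- sort(unique(c(as.character(xA), as.character(xB))))
    sapply(lev, function(l) as.numeric(as.character(x) == l))
  }
  mA <- code_cols(xA); mB <- code_cols(xB)
  sd_pool <- sqrt((apply(mA, 2, stats::var) + apply(mB, 2, stats::var)) / 2)
  if (!is.null(idx_A)) { mA <- mA[idx_A, , drop = FALSE]; mB <- mB[idx_B, , drop = FALSE] }
  d <- abs(colMeans(mA) - colMeans(mB)) / sd_pool
  mean(d[is.finite(d)])
}

#' Mean absolute standardized mean difference over matching features
#'
#' @param A,B cohort tables restricted to complete cases.
#' @param matching_features feature names.
#' @param result optional `match_result`; if supplied, the SMD is computed
#'   over the matched subjects (denominator: pre-match pooled SD).
#' @return Mean absolute SMD (scalar).
#' @export
balance_summary <- function(A, B, matching_features, result = NULL) {
  idx_A <- idx_B <- NULL
  if (!is.null(result)) {
    idx_A <- match(result$pairs$id_A, A$subject_id)
    idx_B <- match(result$pairs$id_B, B$subject_id)
  }
  smds <- vapply(matching_features, function(f) {
    feature_smd(A[[f]], B[[f]], idx_A, idx_B)
  }, numeric(1))
  mean(smds)
}

#' Sweep over caliper widths with repeated matchings
#'
#' For each caliper, `n_repeats` seeded matchings are performed and the
#' matched sample size and covariate balance (mean absolute standardized
#' mean difference over the matching features) are averaged.
#'
#' @param A,B cohort tables.
#' @param matching_features feature names.
#' @param calipers positive caliper fractions (default the study's sweep
#'   `c(1.5, 1.3, 1, 0.7, 0.5, 0.3, 0.1)`).
#' @param n_repeats matchings per caliper.
#' @param seed master seed.
#' @param rule selection rule passed to [caliper_match()].
#' @return data.frame with one row per caliper: `caliper`,
#'   `mean_matched_n`, `mean_balance` and the pre-match `balance_unmatched`.
#' @export
caliper_sweep <- function(A, B, matching_features,
                          calipers = c(1.5, 1.3, 1, 0.7, 0.5, 0.3, 0.1),
                          n_repeats = 100, seed = 1L,
                          rule = "random_within_caliper") {
  if (!length(calipers) || any(calipers <= 0)) stop("calipers must be positive")
  model <- fit_propensity(A, B, matching_features)
  Ac <- complete_cases(A, matching_features)
  Bc <- complete_cases(B, matching_features)
  seeds <- matrix(child_seeds(seed, length(calipers) * n_repeats),
                  nrow = length(calipers))
  pre <- balance_summary(Ac, Bc, matching_features)
  rows <- lapply(seq_along(calipers), function(k) {
    ns <- numeric(n_repeats); bal <- numeric(n_repeats)
    for (r in seq_len(n_repeats)) {
      res <- caliper_match(model, caliper_fraction = calipers[k],
                           rule = rule, seed = seeds[k, r])
      ns[r] <- nrow(res$pairs)
      bal[r] <- if (ns[r] > 0) balance_summary(Ac, Bc, matching_features, res) else NA_real_
    }
    data.frame(caliper = calipers[k], mean_matched_n = mean(ns),
               mean_balance = mean(bal, na.rm = TRUE),
               balance_unmatched = pre)
  })
  do.call(rbind, rows)
}
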