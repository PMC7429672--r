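#' @title Time-to-dementia risk models
#' @description Trains and applies the risk model that scores a subject's
#'   hazard of converting from cognitively normal / MCI status to a
#'   dementia diagnosis.  Two learners share one interface: stochastic
#'   gradient boosted trees minimising the Cox partial-likelihood loss
#'   (the study's model class) and a plain linear Cox model (fast,
#'   closed-form-checkable).  Performance is assessed by repeated k-fold
#'   cross-validation with Harrell's C, with optional inner-loop
#'   hyperparameter selection.
#' @name survival_model
NULL

# Fixed numeric encoder: continuous columns pass through; character/factor
# columns become numeric via the category label when coercible (APOE4
# counts) or per-category indicators otherwise.  Levels are frozen at fit
# time so prediction matrices always align.
build_encoder <- function(table, features) {
  missing_cols <- setdiff(features, names(table))
  if (length(missing_cols)) {
    stop("model feature(s) not present: ", paste(missing_cols, collapse = ", "))
  }
  enc <- lapply(features, function(f) {
    x <- table[[f]]
    if (is.numeric(x)) return(list(kind = "numeric"))
    num <- suppressWarnings(as.numeric(as.character(x)))
    if (all(is.na(num) == is.na(x))) return(list(kind = "as_numeric"))
    list(kind = "indicator", levels = sort(unique(stats::na.omit(as.character(x)))))
  })
  names(enc) <- features
  enc
}

encode_matrix <- function(table, features, encoder) {
  missing_cols <- setdiff(features, names(table))
  if (length(missing_cols)) {
    stop("model feature(s) not present: ", paste(missing_cols, collapse = ", "))
  }
  cols <- list()
  for (f in features) {
    e <- encoder[[f]]
    x <- table[[f]]
    if (e$kind == "numeric") cols[[f]] <- as.numeric(x)
    else if (e$kind == "as_numeric") cols[[f]] <- suppressWarnings(as.numeric(as.character(x)))
    else for (l in e$levels[-1]) cols[[paste0(f, "=", l)]] <- as.numeric(as.character(x) == l)  # reference-coded
  }
  do.call(cbind, cols)
}

#' Fit a time-to-event risk model
#'
#' @param train cohort table with `time` (> 0) and `event` columns.
#' @param features predictor column names.
#' @param learner `"boosted_cox"` (gradient boosted trees, Cox
#'   partial-likelihood objective) or `"cox_linear"` (proportional-hazards
#'   regression via [survival::coxph()]).
#' @param hyper named list of boosting hyperparameters: `nrounds` (number
#'   of boosting stages), `eta` (learning rate), `subsample` (row
#'   subsampling fraction), `max_depth` (tree depth).  Ignored by
#'   `cox_linear`.
#' @param seed integer seed (training is deterministic given the seed).
#' @return A `risk_model` object.
#' @export
fit_risk_model <- function(train, features,
                           learner = c("boosted_cox", "cox_linear"),
                           hyper = list(nrounds = 300, eta = 0.05,
                                        subsample = 0.75, max_depth = 3),
                           seed = 1L) {
  learner <- match.arg(learner)
  stopifnot(all(c("time", "event") %in% names(train)))
  train <- complete_cases(train, features)
  if (any(train$time <= 0)) stop("all times must be > 0")
  if (sum(train$event) == 0) stop("no events in the training data")
  encoder <- build_encoder(train, features)
  X <- encode_matrix(train, features, encoder)
  fitted <- if (learner == "boosted_cox") {
    default <- list(nrounds = 300, eta = 0.05, subsample = 0.75, max_depth = 3)
    hyper <- utils::modifyList(default, hyper)
    # xgboost Cox objective: label = time, negated for censored subjects
    lab <- ifelse(train$event == 1, train$time, -train$time)
    dtr <- xgboost::xgb.DMatrix(X, label = lab)
    params <- c(list(objective = "survival:cox", nthread = 1),
                hyper[setdiff(names(hyper), "nrounds")])
    with_seed(seed, xgboost::xgb.train(params = params, data = dtr,
                                       nrounds = hyper$nrounds, verbose = 0))
  } else {
    survival::coxph(survival::Surv(train$time, train$event) ~ X,
                    ties = "breslow")
  }
  structure(list(learner = learner, fit = fitted, features = features,
                 encoder = encoder, hyper = hyper, seed = seed),
            class = "risk_model")
}

#' Construct a linear risk model with known coefficients
#'
#' A fixed linear scorer (`score = x %*% beta` on the raw feature
#' columns), useful as an oracle and for applying externally estimated
#' coefficient vectors.
#'
#' @param coefficients named numeric vector (names = feature columns).
#' @return A `risk_model` of learner kind `"linear_fixed"`.
#' @export
risk_model_linear <- function(coefficients) {
  stopifnot(!is.null(names(coefficients)))
  structure(list(learner = "linear_fixed", fit = coefficients,
                 features = names(coefficients), encoder = NULL),
            class = "risk_model")
}

#' Predict risk scores
#'
#' Higher scores mean higher predicted hazard.  For `boosted_cox` the
#' score is the boosted log-hazard margin; for `cox_linear` the linear
#' predictor.  Scores are invariant to row order.
#'
#' @param model a `risk_model`.
#' @param table cohort table containing the model's features.
#' @return Numeric score vector (one finite value per row of `table`).
#' @export
predict_risk <- function(model, table) {
  if (model$learner == "linear_fixed") {
    missing_cols <- setdiff(model$features, names(table))
    if (length(missing_cols)) {
      stop("model feature(s) not present: ", paste(missing_cols, collapse = ", "))
    }
    X <- as.matrix(table[, model$features, drop = FALSE])
    return(as.numeric(X %*% model$fit))
  }
  X <- encode_matrix(table, model$features, model$encoder)
  if (model$learner == "boosted_cox") {
    as.numeric(stats::predict(model$fit, xgboost::xgb.DMatrix(X),
                              outputmargin = TRUE))
  } else {
    as.numeric(X %*% stats::coef(model$fit))
  }
}

# deterministic shuffled k-fold partition: returns a fold label per row
fold_assignments <- function(n, k, seed) {
  with_seed(seed, sample(rep_len(seq_len(k), n)))
}

#' Repeated k-fold cross-validated concordance
#'
#' Outer `k`-fold partition repeated `repeats` times; within each outer
#' training set, an optional inner cross-validation (3-fold) selects the
#' hyperparameter row of `hyper_grid` with the best inner C.  Held-out C
#' is computed per outer fold and averaged.  Folds without any event are
#' skipped with a warning.
#'
#' @param table cohort table with `time`, `event`.
#' @param features predictors.
#' @param learner passed to [fit_risk_model()].
#' @param hyper_grid `NULL` (defaults), a single named list, or a
#'   data.frame whose rows are candidate hyperparameter settings.
#' @param k outer folds (>= 2); `repeats` outer repetitions.
#' @param seed master seed.
#' @return List: `mean_c`, `fold_c` (matrix repeats x k, NA where
#'   skipped), `chosen_hyper`.
#' @export
nested_cv_cindex <- function(table, features, learner = "boosted_cox",
                             hyper_grid = NULL, k = 10, repeats = 10,
                             seed = 1L) {
  stopifnot(k >= 2)
  table <- complete_cases(table, c(features, "time", "event"))
  n <- nrow(table)
  seeds <- child_seeds(seed, repeats * 2 + 1)
  grid <- if (is.data.frame(hyper_grid)) hyper_grid
          else if (is.list(hyper_grid) && length(hyper_grid)) as.data.frame(hyper_grid)
          else NULL
  fold_c <- matrix(NA_real_, nrow = repeats, ncol = k)
  chosen <- list()
  for (r in seq_len(repeats)) {
    fa <- fold_assignments(n, k, seeds[2 * r - 1])
    for (fold in seq_len(k)) {
      test <- table[fa == fold, , drop = FALSE]
      tr <- table[fa != fold, , drop = FALSE]
      if (sum(tr$event) == 0 || sum(test$event) == 0) {
        warning("fold ", fold, " (repeat ", r, ") has no events; skipped")
        next
      }
      hy <- if (is.null(grid) || nrow(grid) == 1) {
        if (is.null(grid)) list() else as.list(grid[1, , drop = FALSE])
      } else {
        select_hyper(tr, features, learner, grid, seed = seeds[2 * r])
      }
      m <- fit_risk_model(tr, features, learner = learner, hyper = hy,
                          seed = seeds[2 * r])
      sc <- predict_risk(m, test)
      fold_c[r, fold] <- tryCatch(harrell_c(sc, test$time, test$event),
                                  error = function(e) NA_real_)
      chosen[[length(chosen) + 1L]] <- hy
    }
  }
  list(mean_c = mean(fold_c, na.rm = TRUE), fold_c = fold_c,
       chosen_hyper = chosen)
}

# inner 3-fold selection of the best hyperparameter row by mean C
select_hyper <- function(train, features, learner, grid, seed) {
  fa <- fold_assignments(nrow(train), 3, seed)
  mean_c <- vapply(seq_len(nrow(grid)), function(g) {
    cs <- vapply(1:3, function(fold) {
      tr <- train[fa != fold, , drop = FALSE]
      te <- train[fa == fold, , drop = FALSE]
      if (sum(tr$event) == 0 || sum(te$event) == 0) return(NA_real_)
      m <- fit_risk_model(tr, features, learner = learner,
                          hyper = as.list(grid[g, , drop = FALSE]), seed = seed)
      tryCatch(harrell_c(predict_risk(m, te), te$time, te$event),
               error = function(e) NA_real_)
    }, numeric(1))
    mean(cs, na.rm = TRUE)
  }, numeric(1))
  as.list(grid[which.max(mean_c), , drop = FALSE])
}
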