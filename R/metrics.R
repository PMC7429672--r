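#' @title Discrimination metrics for censored survival predictions
#' @description Harrell's concordance index and the cumulative/dynamic
#'   time-dependent ROC AUC, the two metrics used to judge risk-model
#'   discrimination on (possibly censored) time-to-event validation data.
#' @name metrics
NULL

#' Harrell's concordance index
#'
#' A pair (i, j) is comparable iff subject i has an observed event and
#' `time_i < time_j`; it is concordant iff `score_i > score_j` (higher
#' score = higher predicted risk), and tied scores count 0.5.
#' `C = (concordant + 0.5 * ties) / comparable`; 0.5 is chance level.
#'
#' @param score numeric risk scores.
#' @param time event/censoring times (> 0).
#' @param event 0/1 event indicators.
#' @return C in \[0, 1\].
#' @export
harrell_c <- function(score, time, event) {
  stopifnot(length(score) == length(time), length(time) == length(event))
  ok <- !(is.na(score) | is.na(time) | is.na(event))
  score <- score[ok]; time <- time[ok]; event <- event[ok]
  comparable <- outer(time, time, "<") & (event == 1)  # row i: event with earlier time
  n_comp <- sum(comparable)
  if (n_comp == 0) stop("no comparable pairs; concordance undefined")
  conc <- sum(comparable & outer(score, score, ">"))
  ties <- sum(comparable & outer(score, score, "=="))
  (conc + 0.5 * ties) / n_comp
}

#' Cumulative/dynamic time-dependent ROC AUC curve
#'
#' At horizon t, cases are subjects with an observed event by t
#' (`event = 1 & time <= t`), controls are subjects still under follow-up
#' beyond t (`time > t`); subjects censored at or before t are excluded.
#' AUC(t) is the rank (Mann-Whitney) statistic of the scores, score ties
#' counting 0.5.  The AUC is undefined (NA) wherever either set is empty
#' — e.g. at month 0, where no conversion can yet have occurred.
#'
#' @param score,time,event as in [harrell_c()].
#' @param grid horizons in months (>= 0).
#' @return A data.frame `month`, `auc`, `n_cases`, `n_controls`.
#' @export
td_auc_curve <- function(score, time, event, grid) {
  if (!length(grid)) stop("empty time grid")
  stopifnot(length(score) == length(time), length(time) == length(event))
  ok <- !(is.na(score) | is.na(time) | is.na(event))
  score <- score[ok]; time <- time[ok]; event <- event[ok]
  rows <- lapply(grid, function(t) {
    case <- event == 1 & time <= t
    ctrl <- time > t
    n1 <- sum(case); n0 <- sum(ctrl)
    auc <- if (n1 == 0 || n0 == 0) NA_real_ else {
      r <- rank(c(score[case], score[ctrl]))  # midranks handle ties as 0.5
      (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
    }
    data.frame(month = t, auc = auc, n_cases = n1, n_controls = n0)
  })
  do.call(rbind, rows)
}

#' Write an AUC(t) curve as CSV
#' @param curve result of [td_auc_curve()] (or a pipeline mean curve).
#' @param path CSV path.
#' @export
write_auc_csv <- function(curve, path) {
  utils::write.csv(curve, path, row.names = FALSE)
  invisible(path)
}
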