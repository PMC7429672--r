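#' @title Bonferroni-adjusted interval comparisons between cohorts
#' @description Declares a continuous feature significantly different when
#'   the multiplicity-adjusted confidence interval of the mean difference
#'   excludes 0, and a categorical feature when at least one per-category
#'   proportion-difference interval does.  Also builds the
#'   random-subsample null for the number of significant differences and
#'   the one-tailed rank-sum comparison of matched vs. random counts.
#' @name comparison
NULL

new_interval <- function(lower, upper, level) {
  stopifnot(lower <= upper || (is.na(lower) || is.na(upper)))
  structure(list(lower = lower, upper = upper, level = level,
                 significant = isTRUE(lower > 0 || upper < 0)),
            class = "cohort_interval")
}

#' @export
print.cohort_interval <- function(x, ...) {
  cat(sprintf("[%.4g, %.4g] at %.5g%% confidence%s\n", x$lower, x$upper,
              100 * x$level, if (x$significant) " (excludes 0)" else ""))
  invisible(x)
}

#' Welch confidence interval of a difference in means
#'
#' Two-sample interval with unequal variances (Welch-Satterthwaite degrees
#' of freedom): `mean(x) - mean(y) +/- t_{level, df} * sqrt(s2x/nx + s2y/ny)`.
#' The `adjusted_level` is the Bonferroni-adjusted confidence level, e.g.
#' `1 - 0.05/m` for m simultaneous intervals.
#'
#' @param x,y numeric samples (missing values dropped; each needs >= 2
#'   non-missing values).
#' @param adjusted_level confidence level in (0, 1).
#' @return A `cohort_interval` with `lower`, `upper`, `level`,
#'   `significant` (true iff the interval excludes 0).
#' @export
mean_diff_ci <- function(x, y, adjusted_level = 0.95) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2) {
    stop("need >= 2 non-missing values in each sample")
  }
  d <- mean(x) - mean(y)
  vx <- stats::var(x) / length(x)
  vy <- stats::var(y) / length(y)
  se <- sqrt(vx + vy)
  if (se == 0) return(new_interval(d, d, adjusted_level))
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  tq <- stats::qt(1 - (1 - adjusted_level) / 2, df)
  new_interval(d - tq * se, d + tq * se, adjusted_level)
}

#' Wald confidence interval of a difference in proportions
#'
#' `(p1 - p2) +/- z_{level} * sqrt(p1(1-p1)/n1 + p2(1-p2)/n2)`.
#'
#' @param k1,n1 successes and sample size of the first group.
#' @param k2,n2 successes and sample size of the second group.
#' @param adjusted_level confidence level in (0, 1).
#' @return A `cohort_interval`.
#' @export
proportion_diff_ci <- function(k1, n1, k2, n2, adjusted_level = 0.95) {
  if (n1 < 1 || n2 < 1) stop("sample sizes must be >= 1")
  if (k1 < 0 || k1 > n1 || k2 < 0 || k2 > n2) stop("counts must satisfy 0 <= k <= n")
  p1 <- k1 / n1; p2 <- k2 / n2
  se <- sqrt(p1 * (1 - p1) / n1 + p2 * (1 - p2) / n2)
  zq <- stats::qnorm(1 - (1 - adjusted_level) / 2)
  new_interval(p1 - p2 - zq * se, p1 - p2 + zq * se, adjusted_level)
}

#' Count significantly different features between two cohorts
#'
#' Each continuous feature contributes one Welch mean-difference interval;
#' each categorical feature contributes one Wald proportion-difference
#' interval per category.  All intervals are computed at the
#' Bonferroni-adjusted level `1 - alpha/m` where `m` is the total number
#' of intervals.  A feature counts as different if at least one of its
#' intervals excludes 0.  Samples are pairwise-complete per feature.
#'
#' @param A,B cohort tables.
#' @param dictionary a [data_dictionary()] listing the comparison features.
#' @param alpha familywise error level (default 0.05).
#' @return A `comparison_report`: `intervals` (data.frame `feature`,
#'   `category`, `lower`, `upper`, `significant`), `count` of significant
#'   features, `m`, `alpha`.
#' @export
count_significant_differences <- function(A, B, dictionary, alpha = 0.05) {
  if (nrow(dictionary) == 0) stop("empty feature dictionary")
  n_int <- ifelse(dictionary$kind == "categorical",
                  vapply(dictionary$categories, length, integer(1)), 1L)
  m <- sum(n_int)
  level <- 1 - alpha / m
  rows <- vector("list", nrow(dictionary))
  sig_feature <- logical(nrow(dictionary))
  for (i in seq_len(nrow(dictionary))) {
    f <- dictionary$name[i]
    a <- A[[f]]; b <- B[[f]]
    if (dictionary$kind[i] == "continuous") {
      ci <- mean_diff_ci(a, b, level)
      rows[[i]] <- data.frame(feature = f, category = NA_character_,
                              lower = ci$lower, upper = ci$upper,
                              significant = ci$significant,
                              stringsAsFactors = FALSE)
      sig_feature[i] <- ci$significant
    } else {
      a <- a[!is.na(a)]; b <- b[!is.na(b)]
      cats <- as.character(dictionary$categories[[i]])
      sub <- lapply(cats, function(cl) {
        ci <- proportion_diff_ci(sum(a == cl), length(a),
                                 sum(b == cl), length(b), level)
        data.frame(feature = f, category = cl, lower = ci$lower,
                   upper = ci$upper, significant = ci$significant,
                   stringsAsFactors = FALSE)
      })
      sub <- do.call(rbind, sub)
      rows[[i]] <- sub
      sig_feature[i] <- any(sub$significant)
    }
  }
  structure(list(intervals = do.call(rbind, rows),
                 count = sum(sig_feature), m = m, alpha = alpha),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("%d of %d features significantly different (m = %d intervals, alpha = %g)\n",
              x$count, length(unique(x$intervals$feature)), x$m, x$alpha))
  invisible(x)
}

#' Significant-difference counts on random subsamples
#'
#' The null reference for matched comparisons: draw without-replacement
#' subsamples of the stated sizes from each cohort and count the
#' significant differences, `n_reps` times.
#'
#' @param A,B cohort tables.
#' @param dictionary comparison feature dictionary.
#' @param size_A,size_B subsample sizes (scalars, or vectors of length
#'   `n_reps` to mirror per-repetition matched sample sizes).
#' @param n_reps number of repetitions.
#' @param alpha familywise level.
#' @param seed master seed.
#' @return Integer vector of length `n_reps`.
#' @export
random_subsample_counts <- function(A, B, dictionary, size_A, size_B,
                                    n_reps = 100, alpha = 0.05, seed = 1L) {
  size_A <- rep_len(size_A, n_reps)
  size_B <- rep_len(size_B, n_reps)
  if (any(size_A > nrow(A)) || any(size_B > nrow(B))) {
    stop("requested subsample size exceeds available subjects")
  }
  seeds <- child_seeds(seed, n_reps)
  vapply(seq_len(n_reps), function(r) {
    idx <- with_seed(seeds[r], list(a = sample.int(nrow(A), size_A[r]),
                                    b = sample.int(nrow(B), size_B[r])))
    count_significant_differences(A[idx$a, , drop = FALSE],
                                  B[idx$b, , drop = FALSE],
                                  dictionary, alpha)$count
  }, integer(1))
}

#' One-tailed rank-sum test of matched vs. random difference counts
#'
#' Tests whether the numbers of significant differences found between
#' matched sub-cohorts are stochastically smaller than those found
#' between random subsamples of the same size (two-sample Wilcoxon
#' rank-sum, alternative "less").  Exact enumeration is used for short
#' tie-free lists (both lengths <= 20), the tie-corrected normal
#' approximation otherwise.
#'
#' @param matched_counts,random_counts integer vectors.
#' @return The one-sided p-value.
#' @export
matched_vs_random_test <- function(matched_counts, random_counts) {
  if (!length(matched_counts) || !length(random_counts)) stop("empty count list")
  ties <- anyDuplicated(c(matched_counts, random_counts)) > 0
  small <- length(matched_counts) <= 20 && length(random_counts) <= 20
  suppressWarnings(
    stats::wilcox.test(matched_counts, random_counts, alternative = "less",
                       exact = small && !ties, correct = TRUE)$p.value)
}
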