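# Shared fixtures and independent oracles, built in code at test time.

# Minimal two-feature spec with optional cohort-B shifts and hazard loadings.
simple_spec <- function(nA = c(CN = 100, MCI = 100, DEM = 0),
                        nB = c(CN = 100, MCI = 100, DEM = 0),
                        age_shift_B = 0, x_shift_B = 0,
                        age_loading = 0, x_loading = 0,
                        baseline_hazard = 0, horizon = 84,
                        x_missing = 0) {
  shift_spec(
    features = list(
      feature_spec("age", "continuous",
                   params = list(A = c(70, 7),
                                 B = c(70 + age_shift_B, 7)),
                   hazard_loading = age_loading),
      feature_spec("x", "continuous",
                   params = list(A = c(0, 1), B = c(x_shift_B, 1)),
                   hazard_loading = x_loading, missing_rate = x_missing)),
    n = list(A = nA, B = nB),
    horizon = horizon, baseline_hazard = baseline_hazard)
}

# Brute-force Harrell's C: explicit double loop over ordered pairs.
harrell_c_bruteforce <- function(score, time, event) {
  n <- length(score)
  num <- 0; den <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (event[i] == 1 && time[i] < time[j]) {
      den <- den + 1
      if (score[i] > score[j]) num <- num + 1
      else if (score[i] == score[j]) num <- num + 0.5
    }
  }
  if (den == 0) return(NA_real_)
  num / den
}

# Brute-force cumulative/dynamic AUC at horizon t.
td_auc_bruteforce <- function(score, time, event, t) {
  case <- which(event == 1 & time <= t)
  ctrl <- which(time > t)
  if (!length(case) || !length(ctrl)) return(NA_real_)
  num <- 0
  for (i in case) for (j in ctrl) {
    if (score[i] > score[j]) num <- num + 1
    else if (score[i] == score[j]) num <- num + 0.5
  }
  num / (length(case) * length(ctrl))
}

# Exact pair-selection distribution of the sequential random-within-caliper
# matching process: enumerate every processing order of the reference side
# (uniform) and, recursively, every admissible candidate choice (uniform
# among unmatched partners within the threshold).  Returns a matrix
# P[i, j] = probability that reference i is paired with partner j.
match_pair_distribution <- function(score_ref, score_pool, threshold) {
  nr <- length(score_ref); np <- length(score_pool)
  P <- matrix(0, nr, np)
  recurse <- function(order_left, used, prob) {
    if (!length(order_left)) return(invisible(NULL))
    for (k in seq_along(order_left)) {
      i <- order_left[k]
      p_order <- prob / length(order_left)
      cand <- which(!used & abs(score_pool - score_ref[i]) <= threshold)
      rest <- order_left[-k]
      if (!length(cand)) {
        recurse(rest, used, p_order)
      } else {
        for (j in cand) {
          P[i, j] <<- P[i, j] + p_order / length(cand)
          used2 <- used; used2[j] <- TRUE
          recurse(rest, used2, p_order / length(cand))
        }
      }
    }
  }
  recurse(seq_len(nr), rep(FALSE, np), 1)
  P
}

# Empirical pair frequencies of caliper_match_scores over many seeds.
match_pair_frequency <- function(score_A, score_B, caliper_fraction, n_seeds,
                                 score_sd = NULL) {
  nA <- length(score_A); nB <- length(score_B)
  F <- matrix(0, nA, nB)
  names(score_A) <- paste0("a", seq_len(nA))
  names(score_B) <- paste0("b", seq_len(nB))
  for (s in seq_len(n_seeds)) {
    res <- caliper_match_scores(score_A, score_B, score_sd = score_sd,
                                caliper_fraction = caliper_fraction,
                                rule = "random_within_caliper", seed = s)
    ia <- match(res$pairs$id_A, names(score_A))
    ib <- match(res$pairs$id_B, names(score_B))
    for (k in seq_along(ia)) F[ia[k], ib[k]] <- F[ia[k], ib[k]] + 1
  }
  F / n_seeds
}

# Survival table with a single informative covariate (exponential PH).
simulate_survival_table <- function(n, loading, event_scale = 0.01,
                                    horizon = 84, seed = 1) {
  set.seed(seed)
  x <- rnorm(n)
  t_raw <- rexp(n, rate = event_scale * exp(loading * x))
  data.frame(subject_id = paste0("s", seq_len(n)), cohort = "A",
             diagnosis = "MCI", x = x,
             time = pmin(t_raw, horizon),
             event = as.integer(t_raw <= horizon),
             stringsAsFactors = FALSE)
}
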