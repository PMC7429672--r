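#' @title Cohort tables and data dictionaries
#' @description Helpers for per-subject cohort tables: a plain `data.frame`
#'   with identifier, cohort label, baseline diagnosis, feature columns, and
#'   survival outcome columns (`time` in months, `event` in 0/1), typed by a
#'   data dictionary that declares each feature continuous or categorical.
#' @name cohort_table
NULL

#' Build a feature data dictionary
#'
#' The dictionary types every comparison/matching feature so that downstream
#' operations know whether to compare means (continuous) or per-category
#' proportions (categorical).
#'
#' @param name character vector of feature names.
#' @param kind character vector, each `"continuous"` or `"categorical"`.
#' @param categories list of category label vectors, one per feature
#'   (`NULL` entries for continuous features).
#' @return A `data.frame` with columns `name`, `kind` and a list column
#'   `categories`.
#' @export
data_dictionary <- function(name, kind, categories = NULL) {
  stopifnot(length(name) == length(kind))
  kind <- match.arg(kind, c("continuous", "categorical"), several.ok = TRUE)
  if (is.null(categories)) categories <- vector("list", length(name))
  stopifnot(length(categories) == length(name))
  for (i in seq_along(name)) {
    if (kind[i] == "categorical" && length(categories[[i]]) < 2) {
      stop("categorical feature '", name[i], "' needs >= 2 category labels")
    }
  }
  out <- data.frame(name = as.character(name), kind = kind,
                    stringsAsFactors = FALSE)
  out$categories <- categories
  out
}

#' Write / read a data dictionary as JSON
#'
#' @param dictionary a dictionary from [data_dictionary()].
#' @param path file path of the JSON sidecar.
#' @return `read_dictionary` returns the dictionary `data.frame`.
#' @export
write_dictionary <- function(dictionary, path) {
  entries <- lapply(seq_len(nrow(dictionary)), function(i) {
    e <- list(name = dictionary$name[i], kind = dictionary$kind[i])
    if (dictionary$kind[i] == "categorical") {
      e$categories <- as.character(dictionary$categories[[i]])
    }
    e
  })
  jsonlite::write_json(entries, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_dictionary
#' @export
read_dictionary <- function(path) {
  entries <- jsonlite::read_json(path)
  data_dictionary(
    name = vapply(entries, `[[`, character(1), "name"),
    kind = vapply(entries, `[[`, character(1), "kind"),
    categories = lapply(entries, function(e) {
      if (is.null(e$categories)) NULL else unlist(e$categories)
    })
  )
}

#' Write / read a cohort table as CSV
#'
#' @param table a cohort table `data.frame`.
#' @param path CSV path.
#' @export
write_cohort_csv <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, colClasses = NA)
}

#' Restrict a table to subjects complete for a feature set
#'
#' Matching operates on complete cases with respect to the matching features
#' only; per-feature comparisons use pairwise-complete samples instead.
#'
#' @param table cohort table.
#' @param features character vector of column names.
#' @return The rows of `table` with no missing value in `features`.
#' @export
complete_cases <- function(table, features) {
  missing_cols <- setdiff(features, names(table))
  if (length(missing_cols)) {
    stop("features not present in table: ", paste(missing_cols, collapse = ", "))
  }
  keep <- stats::complete.cases(table[, features, drop = FALSE])
  table[keep, , drop = FALSE]
}

# --- internal RNG helpers -------------------------------------------------

# Evaluate expr under a local seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Deterministically derive n child seeds (< 2^31) from a master seed.
child_seeds <- function(master_seed, n) {
  with_seed(master_seed, sample.int(.Machine$integer.max, n))
}

# Numeric coding of a feature column: continuous stays numeric; categorical
# uses the label's numeric value when coercible (e.g. APOE4 allele counts),
# otherwise positional codes over the sorted observed categories.
numeric_code <- function(x) {
  if (is.numeric(x)) return(x)
  xc <- as.character(x)
  num <- suppressWarnings(as.numeric(xc))
  if (all(is.na(num) == is.na(xc))) return(num)
  lev <- sort(unique(stats::na.omit(xc)))
  as.numeric(match(xc, lev) - 1)
}
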