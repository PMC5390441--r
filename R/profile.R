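#' Default missing-value markers and date patterns
#'
#' Cells equal to one of `na_strings` (after trimming whitespace) are treated
#' as missing and excluded from all statistics. Date patterns are tried in
#' order; ISO 8601 first.
#'
#' @name profile-defaults
#' @keywords internal
NULL

default_na_strings <- function() c("", "NA", "NaN", ".", "NULL")

default_date_formats <- function() {
  c("%Y-%m-%d", "%Y/%m/%d", "%d.%m.%Y", "%m/%d/%Y", "%d/%m/%Y")
}

mark_missing <- function(values, na_strings = default_na_strings()) {
  x <- trimws(as.character(values))
  x[is.na(x) | x %in% na_strings] <- NA_character_
  x
}

parse_number_cells <- function(x) suppressWarnings(as.numeric(x))

parse_date_cells <- function(x, date_formats = default_date_formats()) {
  out <- rep(as.Date(NA), length(x))
  todo <- !is.na(x)
  for (fmt in date_formats) {
    if (!any(todo)) break
    parsed <- as.Date(x[todo], format = fmt)
    # reject parses that drop information (e.g. "%Y" matching "12.05")
    ok <- !is.na(parsed)
    out[which(todo)[ok]] <- parsed[ok]
    todo[todo] <- !ok
  }
  out
}

#' Infer the storage type of a column of raw cell texts
#'
#' A column is `number` when at least `threshold` of its non-missing cells
#' parse as numerals, `date` when at least `threshold` parse under one of the
#' configured date patterns, and `string` otherwise. When both thresholds are
#' met, `number` takes precedence: a numeric column is never reclassified as
#' a date.
#'
#' @param values Vector of raw cell values (coerced to character).
#' @param na_strings Markers treated as missing.
#' @param date_formats Date patterns tried in order.
#' @param threshold Fraction of non-missing cells that must parse, default 0.95.
#' @return One of `"number"`, `"date"`, `"string"`.
#' @export
#' @examples
#' infer_dtype(c("1.2", "3", "4.5"))
#' infer_dtype(c("2001-03-04", "1999-12-31"))
#' infer_dtype(c("1", "2", "x", "y", "z"))
infer_dtype <- function(values, na_strings = default_na_strings(),
                        date_formats = default_date_formats(),
                        threshold = 0.95) {
  x <- mark_missing(values, na_strings)
  x <- x[!is.na(x)]
  if (length(x) == 0) {
    warn("all-missing column; dtype set to 'string'")
    return("string")
  }
  if (mean(!is.na(parse_number_cells(x))) >= threshold) return("number")
  if (mean(!is.na(parse_date_cells(x, date_formats))) >= threshold) return("date")
  "string"
}

#' Infer the scale level of a column
#'
#' Scale levels follow the usual measurement hierarchy: `dichotomous` for at
#' most two distinct values, `ratio` for numeric columns with more than
#' `k_scale` distinct values, `ordinal` for numeric columns with 3 to
#' `k_scale` levels, and `nominal` otherwise.
#'
#' @param values Parsed non-missing values (numeric for `dtype = "number"`).
#' @param dtype Storage type as returned by [infer_dtype()].
#' @param k_scale Maximum number of levels still treated as ordinal for
#'   numeric columns, default 10.
#' @return One of `"ratio"`, `"ordinal"`, `"nominal"`, `"dichotomous"`.
#' @export
infer_scale <- function(values, dtype, k_scale = 10) {
  values <- values[!is.na(values)]
  if (length(values) == 0) {
    warn("empty column; scale set to 'nominal'")
    return("nominal")
  }
  n_values <- dplyr::n_distinct(values)
  if (n_values <= 2) return("dichotomous")
  if (dtype == "number" && n_values > k_scale) return("ratio")
  if (dtype == "number") return("ordinal")
  "nominal"
}

#' Profile one variable into its metadata features
#'
#' Computes the per-variable feature profile that allocation rules operate
#' on: name, optional label, storage type, scale level, number of distinct
#' values, proportion of the most frequent value, and (for numeric columns)
#' median and interquartile range. Quantiles use linear interpolation between
#' order statistics (type 7).
#'
#' For numeric columns, value statistics are computed over the cells that
#' parse as numerals; `n_nonmissing` counts exactly the cells entering that
#' tally, so `prop_most_frequent * n_nonmissing` is always an integer count.
#'
#' @param name Variable name.
#' @param values Raw cell values.
#' @param label Optional human-readable label.
#' @inheritParams infer_dtype
#' @inheritParams infer_scale
#' @return A one-row tibble with columns `name`, `label`, `dtype`, `scale`,
#'   `n_values`, `prop_most_frequent`, `median`, `iqr`, `n_nonmissing`.
#' @export
#' @examples
#' profile_variable("chol", c(1, 2, 3, 4, 100))
profile_variable <- function(name, values, label = NULL,
                             na_strings = default_na_strings(),
                             date_formats = default_date_formats(),
                             threshold = 0.95, k_scale = 10) {
  x <- mark_missing(values, na_strings)
  dtype <- infer_dtype(x, na_strings, date_formats, threshold)
  obs <- x[!is.na(x)]
  med <- iqr <- NA_real_
  if (dtype == "number") {
    num <- parse_number_cells(obs)
    num <- num[!is.na(num)]
    vals <- num
    if (length(num) > 0) {
      qs <- unname(quantile(num, c(0.25, 0.5, 0.75), type = 7))
      med <- qs[2]
      iqr <- qs[3] - qs[1]
    }
  } else {
    vals <- obs
  }
  n_nonmissing <- length(vals)
  if (n_nonmissing == 0) {
    n_values <- 0L
    prop_mf <- NA_real_
    scale <- infer_scale(vals, dtype, k_scale)
  } else {
    tab <- table(vals)
    n_values <- length(tab)
    prop_mf <- max(tab) / n_nonmissing
    scale <- infer_scale(vals, dtype, k_scale)
  }
  tibble::tibble(
    name = as.character(name),
    label = if (is.null(label) || is.na(label)) NA_character_ else as.character(label),
    dtype = dtype, scale = scale,
    n_values = as.integer(n_values),
    prop_most_frequent = prop_mf,
    median = med, iqr = iqr,
    n_nonmissing = as.integer(n_nonmissing)
  )
}

#' Profile every column of a dataset
#'
#' @param data A data frame: one row per participant, one column per variable.
#' @param labels Optional variable labels: either a data frame with columns
#'   `name` and `label` (the sidecar format), or a named character vector.
#'   Variables absent from the map get an absent label.
#' @inheritParams profile_variable
#' @return A tibble with one row per column, in column order.
#' @export
profile_dataset <- function(data, labels = NULL,
                            na_strings = default_na_strings(),
                            date_formats = default_date_formats(),
                            threshold = 0.95, k_scale = 10) {
  stopifnot(is.data.frame(data))
  nms <- names(data)
  dups <- unique(nms[duplicated(nms)])
  if (length(dups) > 0) {
    abort(paste0("duplicate column names: ", paste(dups, collapse = ", ")))
  }
  label_map <- label_lookup(labels)
  purrr::map_dfr(nms, function(nm) {
    profile_variable(
      nm, data[[nm]], label = label_map[[nm]],
      na_strings = na_strings, date_formats = date_formats,
      threshold = threshold, k_scale = k_scale
    )
  })
}

label_lookup <- function(labels) {
  if (is.null(labels)) return(list())
  if (is.data.frame(labels)) {
    stopifnot(all(c("name", "label") %in% names(labels)))
    return(stats::setNames(as.list(as.character(labels$label)), labels$name))
  }
  as.list(labels)
}

#' Read a cohort dataset and its optional label sidecar
#'
#' @param path Path to an RFC-4180 CSV with a header row of variable names.
#' @param labels_path Optional path to a `name,label` sidecar CSV.
#' @return A list with elements `data` (tibble, all columns read as
#'   character) and `labels` (tibble or `NULL`).
#' @export
read_cohort <- function(path, labels_path = NULL) {
  if (!file.exists(path)) abort(paste0("dataset file not found: ", path))
  data <- tibble::as_tibble(read.csv(path, colClasses = "character",
                                     check.names = FALSE))
  labels <- NULL
  if (!is.null(labels_path)) {
    if (!file.exists(labels_path)) {
      abort(paste0("label sidecar not found: ", labels_path))
    }
    labels <- tibble::as_tibble(read.csv(labels_path, colClasses = "character",
                                         check.names = FALSE))
  }
  list(data = data, labels = labels)
}
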