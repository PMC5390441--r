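#' Packaged cohort manifest
#'
#' The manifest of the 34 cohort datasets of the motivating harmonization
#' project (acronym, study name and type, size, and the construction /
#' validation assignment). The underlying participant-level data are not
#' distributed; the manifest documents the scale of the problem and drives
#' the aggregation helpers.
#'
#' @return Tibble with 34 rows.
#' @export
cohort_manifest <- function() {
  path <- system.file("extdata", "cohort_manifest.csv", package = "harmonizr",
                      mustWork = TRUE)
  tibble::as_tibble(read.csv(path, check.names = FALSE))
}

#' Packaged per-target reference performance table
#'
#' Sensitivity, specificity, PPV and NPV of the fitted Boolean rule
#' combinations for the 41 target variables, in the construction and the
#' validation sample of the motivating project. Shipped as an aggregation
#' fixture: the source datasets are not available, so these values are
#' reference content, not outputs recomputed by this package.
#'
#' @param include_average Keep the final `Average` row?
#' @return Tibble with 41 target rows (plus the Average row if requested).
#' @export
target_performance <- function(include_average = FALSE) {
  path <- system.file("extdata", "target_performance.csv",
                      package = "harmonizr", mustWork = TRUE)
  out <- tibble::as_tibble(read.csv(path, check.names = FALSE,
                                    na.strings = character()))
  out$unit <- as.character(out$unit)
  if (!include_average) out <- out[out$target != "Average", , drop = FALSE]
  out
}
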