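#' Factor levels of the packaged tuning grid
#'
#' Two scoring methods, four negative-class weights spanning 5e-4 to 0.5,
#' two tree sizes and two minmass values: a 2^3 x 4 hybrid factorial grid of
#' 32 runs.
#'
#' @return Named list of factor levels.
#' @export
default_design_levels <- function() {
  list(
    method = c("classification", "logistic"),
    w_neg = c(5e-4, 5e-3, 5e-2, 5e-1),
    treesize = c(5L, 10L),
    minmass = c(4L, 8L)
  )
}

#' Generate a full factorial design
#'
#' @param levels Named list mapping each factor to its level vector.
#' @return A tibble with one row per design point: the full Cartesian
#'   product in deterministic lexicographic order (each factor's levels
#'   sorted ascending, leftmost factor most significant).
#' @export
#' @examples
#' nrow(generate_design(default_design_levels()))
generate_design <- function(levels = default_design_levels()) {
  if (length(levels) == 0 || any(lengths(levels) == 0)) {
    abort("every factor needs at least one level")
  }
  do.call(tidyr::crossing, lapply(levels, unique))
}

#' Grouped k-fold cross-validation of one target's annealing fit
#'
#' Splits the instances into `k` folds, fits a tree on each training
#' complement and predicts the held-out fold, so every instance is predicted
#' exactly once by a model fitted without it. With `grouped = TRUE` (the
#' default) folds are formed over source datasets, keeping all variables of
#' a dataset in the same fold so dataset-specific naming conventions cannot
#' leak between training and test.
#'
#' @param instances A list with elements `rule_matrix` (0/1 matrix),
#'   `labels` (binary vector) and `groups` (dataset id per instance), as
#'   produced per target by [build_instances()].
#' @param config An [anneal_config()]; per-fold fits derive their seeds from
#'   `config$seed` and `seed`.
#' @param k Number of folds, at least 2.
#' @param grouped Group folds by source dataset?
#' @param seed Seed for the fold assignment.
#' @return List with `folds` (per-fold confusion metrics; a fold without
#'   positives reports sensitivity `NA` with a warning) and `pooled`
#'   (metrics pooled over all held-out predictions).
#' @export
cross_validate <- function(instances, config = anneal_config(), k = 10L,
                           grouped = TRUE, seed = 1L) {
  stopifnot(k >= 2)
  n <- length(instances$labels)
  fold_of <- withr::with_seed(seed, {
    if (grouped) {
      groups <- unique(instances$groups)
      if (length(groups) < k) {
        abort(paste0("grouped cross-validation needs at least k = ", k,
                     " datasets, got ", length(groups)))
      }
      assignment <- stats::setNames(
        rep_len(seq_len(k), length(groups))[sample.int(length(groups))],
        groups
      )
      assignment[instances$groups]
    } else {
      rep_len(seq_len(k), n)[sample.int(n)]
    }
  })
  held_out_pred <- logical(n)
  fold_rows <- purrr::map_dfr(seq_len(k), function(f) {
    test <- fold_of == f
    if (sum(instances$labels[!test]) == 0) {
      warn(paste0("fold ", f, ": training data has no positives; ",
                  "predicting negative for the held-out fold"))
      pred <- rep(FALSE, sum(test))
    } else {
      fit <- anneal(instances$rule_matrix[!test, , drop = FALSE],
                    instances$labels[!test],
                    modify_config(config, seed = derive_seed(config$seed, f)))
      pred <- predict(fit, instances$rule_matrix[test, , drop = FALSE])
    }
    held_out_pred[test] <<- pred
    metrics <- compute_metrics(pred, instances$labels[test])
    if (sum(instances$labels[test]) == 0) {
      warn(paste0("fold ", f, " has no positives; sensitivity undefined"))
    }
    dplyr::mutate(metrics, fold = f, .before = 1)
  })
  list(folds = fold_rows,
       pooled = compute_metrics(held_out_pred, instances$labels))
}

modify_config <- function(config, ...) {
  changes <- list(...)
  for (nm in names(changes)) config[[nm]] <- changes[[nm]]
  anneal_config(method = config$method, weights = config$weights,
                treesize = config$treesize, minmass = config$minmass,
                p_start = config$p_start, p_end = config$p_end,
                n_iterations = config$n_iterations, seed = config$seed)
}

#' Run a tuning design over one target's instances
#'
#' Evaluates every design point by grouped cross-validation and reports the
#' pooled (micro-averaged) sensitivity and specificity per point.
#'
#' @param design Design tibble from [generate_design()].
#' @param instances Per-target instances, see [cross_validate()].
#' @param base_config Template [anneal_config()]; each design point
#'   overrides `method`, `weights`, `treesize` and `minmass`.
#' @inheritParams cross_validate
#' @return The design tibble with `sensitivity`, `specificity` and a
#'   list-column `folds` of per-fold metrics, classed `design_results`.
#' @export
tune_design <- function(design, instances, base_config = anneal_config(),
                        k = 10L, grouped = TRUE, seed = 1L) {
  rows <- purrr::map_dfr(seq_len(nrow(design)), function(i) {
    point <- design[i, ]
    config <- modify_config(base_config,
                            method = point$method,
                            weights = score_weights(point$w_neg),
                            treesize = point$treesize,
                            minmass = point$minmass,
                            seed = derive_seed(base_config$seed, i))
    cv <- cross_validate(instances, config, k = k, grouped = grouped,
                         seed = seed)
    dplyr::mutate(point,
                  sensitivity = cv$pooled$sensitivity,
                  specificity = cv$pooled$specificity,
                  folds = list(cv$folds))
  })
  class(rows) <- c("design_results", class(rows))
  rows
}

#' Select the operating configuration from tuning results
#'
#' Among design points meeting both the sensitivity and the specificity
#' floor, returns the one with maximal sensitivity (ties broken by
#' specificity, then by lexicographic factor order). If no point meets both
#' floors, the sensitivity floor is dropped first (maximal sensitivity
#' subject to the specificity floor); if still empty, the point with
#' maximal sensitivity overall is returned. The applied relaxation is
#' reported in the `relaxation` column.
#'
#' @param results Tibble with factor columns and `sensitivity` /
#'   `specificity` (e.g. from [tune_design()]).
#' @param sens_floor,spec_floor Lower limits for sensitivity and
#'   specificity.
#' @return One-row tibble: the selected design point plus `relaxation`
#'   (`"none"`, `"sens_floor_dropped"` or `"all_floors_dropped"`).
#' @export
select_config <- function(results, sens_floor = 0.99, spec_floor = 0.75) {
  if (nrow(results) == 0) abort("no tuning results supplied")
  factor_cols <- intersect(c("method", "w_neg", "treesize", "minmass"),
                           names(results))
  ordered <- results |>
    dplyr::arrange(dplyr::desc(.data$sensitivity),
                   dplyr::desc(.data$specificity),
                   dplyr::across(dplyr::all_of(factor_cols)))
  tiers <- list(
    none = ordered |>
      dplyr::filter(.data$sensitivity >= sens_floor,
                    .data$specificity >= spec_floor),
    sens_floor_dropped = ordered |>
      dplyr::filter(.data$specificity >= spec_floor),
    all_floors_dropped = ordered
  )
  for (relax in names(tiers)) {
    if (nrow(tiers[[relax]]) > 0) {
      out <- tiers[[relax]][1, ]
      out$folds <- NULL
      return(dplyr::mutate(tibble::as_tibble(out), relaxation = relax))
    }
  }
}
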