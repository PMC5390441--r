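#' Build per-target labeled instances from profiles and gold mappings
#'
#' For every target of the registry, each (dataset, variable) pair becomes
#' one instance: the rule matrix holds the target's rule evaluations on the
#' variable's metadata profile, and the label is 1 exactly when the gold
#' mapping assigns that variable to the target. A variable mapped to target
#' A is therefore a negative instance for every other target.
#'
#' @param profiles Metadata profiles of one or more datasets, with a
#'   `dataset_id` column (stack [profile_dataset()] outputs).
#' @param registry Rule registry.
#' @param gold Gold mapping tibble with columns `dataset_id`,
#'   `source_variable`, `target_name`. At most one source variable per
#'   (dataset, target); every referenced variable must exist in its
#'   dataset's profiles.
#' @return A named list (one element per target) of instance sets:
#'   `target_name`, `rule_matrix`, `labels`, `groups` (dataset ids),
#'   `variables` (source variable names).
#' @export
build_instances <- function(profiles, registry, gold) {
  stopifnot("dataset_id" %in% names(profiles))
  key <- paste(profiles$dataset_id, profiles$name, sep = "\r")
  gold_key <- paste(gold$dataset_id, gold$source_variable, sep = "\r")
  dangling <- gold[!gold_key %in% key, , drop = FALSE]
  if (nrow(dangling) > 0) {
    abort(paste0(
      "gold mappings reference variables absent from the profiles: ",
      paste(paste0(dangling$dataset_id, "/", dangling$source_variable),
            collapse = ", ")))
  }
  dup <- gold |>
    dplyr::count(.data$dataset_id, .data$target_name) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(paste0("more than one gold source for: ",
                 paste(paste0(dup$dataset_id, "/", dup$target_name),
                       collapse = ", ")))
  }
  unknown <- setdiff(unique(gold$target_name), unique(registry$target_name))
  if (length(unknown) > 0) {
    abort(paste0("gold mappings name targets absent from the registry: ",
                 paste(unknown, collapse = ", ")))
  }
  targets <- unique(registry$target_name)
  out <- lapply(targets, function(tn) {
    g <- gold[gold$target_name == tn, , drop = FALSE]
    labels <- as.integer(key %in% paste(g$dataset_id, g$source_variable,
                                        sep = "\r"))
    list(target_name = tn,
         rule_matrix = evaluate_ruleset(registry, tn, profiles),
         labels = labels,
         groups = profiles$dataset_id,
         variables = profiles$name)
  })
  stats::setNames(out, targets)
}

#' Fit one logic tree per target
#'
#' Runs [anneal()] on every target's instances. Targets without a single
#' positive instance cannot be fitted and are skipped with a warning; they
#' are reported in the `skipped` attribute rather than silently dropped.
#' Per-target seeds are derived deterministically from `config$seed`.
#'
#' @param instances Output of [build_instances()].
#' @param config An [anneal_config()].
#' @return Named list of `logic_fit` objects, classed `harmonizr_models`,
#'   with attribute `skipped` (character vector of unfitted targets).
#' @export
fit_all_targets <- function(instances, config = anneal_config()) {
  fitted <- list()
  skipped <- character()
  for (i in seq_along(instances)) {
    inst <- instances[[i]]
    if (sum(inst$labels) == 0) {
      skipped <- c(skipped, inst$target_name)
      next
    }
    fitted[[inst$target_name]] <- anneal(
      inst$rule_matrix, inst$labels,
      modify_config(config, seed = derive_seed(config$seed, i)))
  }
  if (length(skipped) > 0) {
    warn(paste0("targets without positive instances were skipped: ",
                paste(skipped, collapse = ", ")))
  }
  structure(fitted, class = "harmonizr_models", skipped = skipped)
}

#' Rank candidate source variables of a dataset for each target
#'
#' Evaluates each fitted tree on every variable of the dataset. Variables
#' the tree accepts are predicted matches; all candidates are ranked by the
#' fraction of tree leaves they satisfy (complement-aware), ties broken by
#' variable name. The returned list per target holds all predicted-positive
#' candidates and, when these are fewer than `top_k`, the next best-ranked
#' negatives as an escape pathway; a target with no positive prediction
#' yields its `top_k` best-ranked negatives.
#'
#' @param models `harmonizr_models` from [fit_all_targets()].
#' @param registry The registry the models were fitted over.
#' @param profiles Metadata profiles of the dataset(s) to screen; an
#'   optional `dataset_id` column is carried through.
#' @param top_k Minimum list length per (dataset, target).
#' @param rank Rank candidates by satisfied-leaf fraction? With
#'   `rank = FALSE` the `rank_key` is 1/0 by predicted status only.
#' @return Tibble: `dataset_id`, `target_name`, `source_variable`,
#'   `predicted`, `rank_key`, sorted by `rank_key` descending within
#'   (dataset, target).
#' @export
allocate <- function(models, registry, profiles, top_k = 5L, rank = TRUE) {
  if (!"dataset_id" %in% names(profiles)) {
    profiles <- dplyr::mutate(profiles, dataset_id = "dataset", .before = 1)
  }
  purrr::map_dfr(names(models), function(tn) {
    fit <- models[[tn]]
    leaves <- tree_leaves(fit$tree)
    purrr::map_dfr(unique(profiles$dataset_id), function(ds) {
      prof <- profiles[profiles$dataset_id == ds, , drop = FALSE]
      m <- evaluate_ruleset(registry, tn, prof) > 0
      predicted <- evaluate_tree(fit$tree, m)
      if (rank) {
        sat <- rowSums(vapply(seq_len(nrow(leaves)), function(j) {
          v <- m[, leaves$index[j]]
          if (leaves$complement[j]) !v else v
        }, logical(nrow(prof))))
        rank_key <- sat / nrow(leaves)
      } else {
        rank_key <- as.numeric(predicted)
      }
      cand <- tibble::tibble(
        dataset_id = ds, target_name = tn, source_variable = prof$name,
        predicted = predicted, rank_key = rank_key
      ) |>
        dplyr::arrange(dplyr::desc(.data$predicted),
                       dplyr::desc(.data$rank_key), .data$source_variable)
      keep <- max(sum(cand$predicted), min(top_k, nrow(cand)))
      cand[seq_len(keep), , drop = FALSE]
    })
  })
}

#' Confusion-matrix metrics
#'
#' @param predictions,labels Binary vectors of equal length.
#' @return One-row tibble: `tp`, `fp`, `fn`, `tn`, `sensitivity`
#'   (tp/(tp+fn)), `specificity` (tn/(tn+fp)), `ppv` (tp/(tp+fp)), `npv`
#'   (tn/(tn+fn)); each ratio is `NA` exactly when its denominator is 0.
#' @export
#' @examples
#' compute_metrics(c(1, 1, 1, 0), c(1, 0, 1, 0))
compute_metrics <- function(predictions, labels) {
  if (length(predictions) != length(labels)) {
    abort("predictions and labels differ in length")
  }
  p <- as.integer(predictions)
  y <- as.integer(labels)
  tp <- sum(p == 1 & y == 1)
  fp <- sum(p == 1 & y == 0)
  fn <- sum(p == 0 & y == 1)
  tn <- sum(p == 0 & y == 0)
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  tibble::tibble(
    tp = tp, fp = fp, fn = fn, tn = tn,
    sensitivity = ratio(tp, tp + fn),
    specificity = ratio(tn, tn + fp),
    ppv = ratio(tp, tp + fp),
    npv = ratio(tn, tn + fn)
  )
}

#' Evaluate fitted models against gold mappings
#'
#' Screens every variable of every dataset with each target's fitted tree
#' and scores the predictions against the gold mapping, per target and
#' pooled over all (dataset, variable, target) instances.
#'
#' @param models `harmonizr_models`.
#' @param registry Rule registry the models were fitted over.
#' @param profiles Profiles with `dataset_id` column.
#' @param gold Gold mapping tibble.
#' @return List with `per_target` (one metrics row per fitted target) and
#'   `pooled` (one metrics row over all instances).
#' @export
evaluate_models <- function(models, registry, profiles, gold) {
  all_pred <- logical(0)
  all_lab <- integer(0)
  per_target <- purrr::map_dfr(names(models), function(tn) {
    m <- evaluate_ruleset(registry, tn, profiles) > 0
    pred <- evaluate_tree(models[[tn]]$tree, m)
    g <- gold[gold$target_name == tn, , drop = FALSE]
    lab <- as.integer(
      paste(profiles$dataset_id, profiles$name) %in%
        paste(g$dataset_id, g$source_variable))
    all_pred <<- c(all_pred, pred)
    all_lab <<- c(all_lab, lab)
    dplyr::mutate(compute_metrics(pred, lab), target_name = tn, .before = 1)
  })
  list(per_target = per_target, pooled = compute_metrics(all_pred, all_lab))
}

#' Per-target performance report with an Average row
#'
#' Joins construction- and validation-sample metrics into one row per
#' target, appends an `Average` row holding the unweighted column means over
#' targets (missing cells are excluded from their column's mean), and
#' reports the fraction of targets with PPV at or below 0.5 in each sample
#' (the share of targets whose positive identifications are wrong at least
#' half the time).
#'
#' @param construction,validation Per-target metric tibbles with columns
#'   `target` (or `target_name`), `sensitivity`, `specificity`, `ppv`,
#'   `npv`, and optionally `unit`.
#' @return A `performance_report`: tibble with 8 metric columns per target
#'   plus the `Average` row; attributes `ppv_le_half` (named vector of the
#'   two fractions) carry the summary line.
#' @export
performance_report <- function(construction, validation) {
  std <- function(df, prefix) {
    if ("target_name" %in% names(df) && !"target" %in% names(df)) {
      df <- dplyr::rename(df, target = "target_name")
    }
    df |>
      dplyr::select(dplyr::any_of(c("target", "unit")), "sensitivity",
                    "specificity", "ppv", "npv") |>
      dplyr::rename_with(~ paste0(prefix, "_", .x),
                         c("sensitivity", "specificity", "ppv", "npv"))
  }
  cw <- std(construction, "construction")
  vw <- std(validation, "validation")
  wide <- dplyr::full_join(cw, vw,
                           by = intersect(c("target", "unit"),
                                          intersect(names(cw), names(vw))))
  metric_cols <- setdiff(names(wide), c("target", "unit"))
  avg <- wide |>
    dplyr::summarise(dplyr::across(dplyr::all_of(metric_cols),
                                   ~ mean(.x, na.rm = TRUE))) |>
    dplyr::mutate(target = "Average", .before = 1)
  if ("unit" %in% names(wide)) avg$unit <- ""
  out <- dplyr::bind_rows(wide, avg)
  ppv_le_half <- c(
    construction = mean(wide$construction_ppv <= 0.5, na.rm = TRUE),
    validation = mean(wide$validation_ppv <= 0.5, na.rm = TRUE)
  )
  structure(out, class = c("performance_report", class(out)),
            ppv_le_half = ppv_le_half)
}

#' @export
print.performance_report <- function(x, ...) {
  NextMethod()
  frac <- attr(x, "ppv_le_half")
  cat(sprintf(
    "PPV <= 0.5 for %.0f%% of targets (construction), %.0f%% (validation)\n",
    100 * frac[["construction"]], 100 * frac[["validation"]]))
  invisible(x)
}

#' Serialize / deserialize fitted models as JSON
#'
#' Each model is stored as its target name, rule ids, rendered Boolean
#' expression, score and configuration echo; `read_models()` parses the
#' expressions back into equivalent trees.
#'
#' @param models `harmonizr_models`.
#' @param path JSON file path.
#' @return `read_models()` returns a `harmonizr_models` object.
#' @export
write_models <- function(models, path) {
  payload <- lapply(names(models), function(tn) {
    fit <- models[[tn]]
    cfg <- fit$config
    list(target = tn, rule_ids = fit$rule_ids,
         expression = tree_to_expression(fit$tree, fit$rule_ids),
         score = fit$score,
         config = list(method = cfg$method, w_neg = cfg$weights$w_neg,
                       treesize = cfg$treesize, minmass = cfg$minmass,
                       p_start = cfg$p_start, p_end = cfg$p_end,
                       n_iterations = cfg$n_iterations, seed = cfg$seed))
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_models
#' @export
read_models <- function(path) {
  if (!file.exists(path)) abort(paste0("model file not found: ", path))
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  models <- list()
  for (entry in payload) {
    rule_ids <- unlist(entry$rule_ids)
    cfg <- entry$config
    models[[entry$target]] <- structure(
      list(tree = parse_expression(entry$expression, rule_ids),
           score = entry$score, trace = numeric(0), n_accepted = NA_integer_,
           rule_ids = rule_ids,
           config = anneal_config(
             method = cfg$method, weights = score_weights(cfg$w_neg),
             treesize = cfg$treesize, minmass = cfg$minmass,
             p_start = cfg$p_start, p_end = cfg$p_end,
             n_iterations = cfg$n_iterations, seed = cfg$seed)),
      class = "logic_fit")
  }
  structure(models, class = "harmonizr_models", skipped = character())
}
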