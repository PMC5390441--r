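rule_kinds <- c("name_contains", "label_contains", "dtype_is", "scale_is",
                "threshold")
threshold_features <- c("median", "iqr", "n_values", "prop_most_frequent")

#' Construct a single allocation rule
#'
#' A rule is a binary predicate on a variable's metadata profile. Substring
#' kinds (`name_contains`, `label_contains`) test case- and
#' accent-insensitive containment; `dtype_is` / `scale_is` test equality of
#' the type or scale level; `threshold` strictly compares a numeric metadata
#' feature against a cutoff. Evaluation is total: a rule whose feature is
#' absent (e.g. a median threshold on a string variable, or a label rule on
#' an unlabelled variable) evaluates to `FALSE`, never to missing.
#'
#' @param id Rule identifier, unique within its target.
#' @param kind One of `r paste(rule_kinds, collapse = ", ")`.
#' @param pattern Substring (substring kinds) or required value
#'   (`dtype_is`/`scale_is`).
#' @param feature,direction,cutoff For `threshold` rules: metadata feature,
#'   comparison direction (`"gt"` or `"lt"`), and cutoff value.
#' @return A one-row tibble.
#' @export
#' @examples
#' rule("r1", "name_contains", pattern = "cholesterol")
#' rule("r2", "threshold", feature = "median", direction = "gt", cutoff = 94)
rule <- function(id, kind, pattern = NULL, feature = NULL, direction = NULL,
                 cutoff = NULL) {
  kind <- match.arg(kind, rule_kinds)
  if (kind == "threshold") {
    if (is.null(feature) || is.null(direction) || is.null(cutoff) ||
        !is.null(pattern)) {
      abort("threshold rules carry feature, direction and cutoff, no pattern")
    }
    feature <- match.arg(feature, threshold_features)
    direction <- match.arg(direction, c("gt", "lt"))
  } else {
    if (is.null(pattern) || !is.null(feature) || !is.null(cutoff)) {
      abort(paste0(kind, " rules carry a pattern and no feature/cutoff"))
    }
  }
  tibble::tibble(
    rule_id = as.character(id), kind = kind,
    pattern = pattern %||% NA_character_,
    feature = feature %||% NA_character_,
    direction = direction %||% NA_character_,
    cutoff = if (is.null(cutoff)) NA_real_ else as.numeric(cutoff)
  )
}

#' Evaluate one rule on one or more metadata profiles
#'
#' @param r A one-row rule tibble (see [rule()]).
#' @param profiles Metadata profiles as returned by [profile_dataset()].
#' @return Logical vector, one element per profile row. Total: inapplicable
#'   comparisons yield `FALSE`.
#' @export
evaluate_rule <- function(r, profiles) {
  stopifnot(nrow(r) == 1)
  out <- switch(r$kind,
    name_contains = stringr::str_detect(
      norm_text(profiles$name), stringr::fixed(norm_text(r$pattern))),
    label_contains = stringr::str_detect(
      norm_text(profiles$label), stringr::fixed(norm_text(r$pattern))),
    dtype_is = profiles$dtype == r$pattern,
    scale_is = profiles$scale == r$pattern,
    threshold = {
      v <- profiles[[r$feature]]
      if (r$direction == "gt") v > r$cutoff else v < r$cutoff
    }
  )
  out[is.na(out)] <- FALSE
  out
}

#' Evaluate a target's full rule set on metadata profiles
#'
#' Produces the binary leaf-input matrix consumed by the logic-regression
#' engine: one row per profile, one column per rule, in the registry's rule
#' order.
#'
#' @param registry A rule registry (see [default_registry()]).
#' @param target_name Name of the target whose rules to evaluate.
#' @param profiles Metadata profiles.
#' @return Integer 0/1 matrix with `rule_id` column names.
#' @export
evaluate_ruleset <- function(registry, target_name, profiles) {
  rules <- registry[registry$target_name == target_name, , drop = FALSE]
  if (nrow(rules) == 0) abort(paste0("unknown target: ", target_name))
  cols <- lapply(seq_len(nrow(rules)), function(i) {
    as.integer(evaluate_rule(rules[i, ], profiles))
  })
  m <- do.call(cbind, cols)
  colnames(m) <- rules$rule_id
  m
}

#' Optimize a threshold-rule cutoff by ROC analysis
#'
#' Chooses the cutoff maximizing sensitivity + specificity. Candidate
#' cutoffs are the midpoints between consecutive sorted distinct feature
#' values, plus -Inf and +Inf sentinels; ties are broken by the smallest
#' cutoff.
#'
#' @param feature_values Numeric feature values (e.g. per-variable medians).
#' @param labels Binary labels aligned with `feature_values` (1 = the
#'   variable matches the target).
#' @param direction `"gt"` to predict positive above the cutoff, `"lt"`
#'   below it.
#' @return A one-row tibble with `cutoff`, `sensitivity`, `specificity`.
#' @export
#' @examples
#' optimize_cutoff(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1), "gt")
optimize_cutoff <- function(feature_values, labels, direction = c("gt", "lt")) {
  direction <- match.arg(direction)
  keep <- !is.na(feature_values) & !is.na(labels)
  v <- as.numeric(feature_values[keep])
  y <- as.integer(labels[keep])
  if (length(unique(y)) < 2) {
    abort("uncalibratable rule: labels must contain both classes")
  }
  s <- sort(unique(v))
  candidates <- c(-Inf, if (length(s) > 1) (head(s, -1) + s[-1]) / 2, Inf)
  best <- NULL
  for (cut in candidates) {
    pred <- if (direction == "gt") v > cut else v < cut
    sens <- sum(pred & y == 1) / sum(y == 1)
    spec <- sum(!pred & y == 0) / sum(y == 0)
    if (is.null(best) || sens + spec > best$obj + 1e-12) {
      best <- list(cutoff = cut, sens = sens, spec = spec, obj = sens + spec)
    }
  }
  tibble::tibble(cutoff = best$cutoff, sensitivity = best$sens,
                 specificity = best$spec)
}

#' Calibrate every threshold rule of a registry against training data
#'
#' Re-optimizes the cutoff of each threshold rule by ROC analysis on labeled
#' training profiles: for a given target, a profile is a positive when the
#' gold mapping assigns that variable to the target. Rules whose labels are
#' one-sided or whose feature is entirely absent keep their authored cutoff,
#' with a warning.
#'
#' @param registry Rule registry.
#' @param profiles Metadata profiles with a `dataset_id` column.
#' @param gold Gold mapping tibble: `dataset_id`, `source_variable`,
#'   `target_name`.
#' @return The registry with updated cutoffs.
#' @export
calibrate_registry <- function(registry, profiles, gold) {
  stopifnot("dataset_id" %in% names(profiles))
  out <- registry
  for (i in seq_len(nrow(out))) {
    r <- out[i, ]
    if (r$kind != "threshold") next
    labels <- as.integer(
      paste(profiles$dataset_id, profiles$name) %in%
        paste(gold$dataset_id[gold$target_name == r$target_name],
              gold$source_variable[gold$target_name == r$target_name])
    )
    values <- profiles[[r$feature]]
    res <- tryCatch(
      optimize_cutoff(values[!is.na(values)], labels[!is.na(values)],
                      r$direction),
      error = function(e) NULL
    )
    if (is.null(res)) {
      warn(paste0("rule ", r$rule_id, " of target '", r$target_name,
                  "' could not be calibrated; keeping cutoff ", r$cutoff))
    } else {
      out$cutoff[i] <- res$cutoff
    }
  }
  out
}

validate_registry_df <- function(df) {
  problems <- character()
  required <- c("target_name", "unit", "rule_id", "kind", "pattern",
                "feature", "direction", "cutoff")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    problems <- c(problems, paste0("missing columns: ",
                                   paste(missing_cols, collapse = ", ")))
  } else {
    if (nrow(df) == 0) problems <- c(problems, "registry has no targets")
    bad_kind <- unique(df$kind[!df$kind %in% rule_kinds])
    if (length(bad_kind) > 0) {
      problems <- c(problems, paste0("unknown rule kind: ",
                                     paste(bad_kind, collapse = ", ")))
    }
    dup <- df |>
      dplyr::count(.data$target_name, .data$rule_id) |>
      dplyr::filter(.data$n > 1)
    if (nrow(dup) > 0) {
      problems <- c(problems, paste0(
        "duplicate rule ids within a target: ",
        paste(paste0(dup$target_name, "/", dup$rule_id), collapse = ", ")))
    }
    units <- df |> dplyr::distinct(.data$target_name, .data$unit)
    dup_t <- units$target_name[duplicated(units$target_name)]
    if (length(dup_t) > 0) {
      problems <- c(problems, paste0("duplicate target names: ",
                                     paste(unique(dup_t), collapse = ", ")))
    }
    thr <- df[!is.na(df$kind) & df$kind == "threshold", , drop = FALSE]
    bad_thr <- thr$rule_id[is.na(thr$feature) | is.na(thr$direction) |
                             is.na(thr$cutoff) | !is.na(thr$pattern)]
    sub <- df[!is.na(df$kind) & df$kind != "threshold", , drop = FALSE]
    bad_sub <- sub$rule_id[is.na(sub$pattern) | !is.na(sub$cutoff)]
    if (length(c(bad_thr, bad_sub)) > 0) {
      problems <- c(problems, paste0("malformed rules: ",
                                     paste(c(bad_thr, bad_sub), collapse = ", ")))
    }
  }
  problems
}

new_registry <- function(df) {
  problems <- validate_registry_df(df)
  if (length(problems) > 0) {
    abort(paste0("invalid registry:\n", paste0("- ", problems, collapse = "\n")))
  }
  tibble::as_tibble(df)
}

#' List the targets of a registry
#'
#' @param registry Rule registry.
#' @return Tibble with `target_name`, `unit` and the rule count per target.
#' @export
registry_targets <- function(registry) {
  registry |>
    dplyr::group_by(.data$target_name, .data$unit) |>
    dplyr::summarise(n_rules = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(match(.data$target_name, unique(registry$target_name)))
}

registry_schema_version <- 1L

#' Read / write a rule registry
#'
#' The on-disk format is YAML (JSON is accepted too, being a YAML subset):
#' a `schema_version` key and a `targets` list, each target carrying
#' `target_name`, `unit` and its ordered `rules`. `read_registry(write_registry(r))`
#' is the identity.
#'
#' @param registry Rule registry tibble.
#' @param path File path.
#' @return `read_registry()` returns the registry tibble.
#' @export
write_registry <- function(registry, path) {
  registry <- new_registry(registry)
  targets <- registry |>
    dplyr::group_by(.data$target_name, .data$unit) |>
    dplyr::group_map(function(rows, key) {
      rules <- lapply(seq_len(nrow(rows)), function(i) {
        r <- as.list(rows[i, c("rule_id", "kind", "pattern", "feature",
                               "direction", "cutoff")])
        r[!vapply(r, is.na, logical(1))]
      })
      list(target_name = key$target_name, unit = key$unit, rules = rules)
    })
  # preserve registry order, not group_by's alphabetical order
  ord <- match(unique(registry$target_name),
               vapply(targets, function(t) t$target_name, character(1)))
  yaml::write_yaml(
    list(schema_version = registry_schema_version, targets = targets[ord]),
    path
  )
  invisible(path)
}

#' @rdname write_registry
#' @export
read_registry <- function(path) {
  if (!file.exists(path)) abort(paste0("registry file not found: ", path))
  doc <- yaml::read_yaml(path)
  if (is.null(doc$schema_version) || is.null(doc$targets)) {
    abort("invalid registry file: needs schema_version and targets keys")
  }
  df <- purrr::map_dfr(doc$targets, function(t) {
    purrr::map_dfr(t$rules, function(r) {
      tibble::tibble(
        target_name = t$target_name %||% NA_character_,
        unit = t$unit %||% "",
        rule_id = r$rule_id %||% NA_character_,
        kind = r$kind %||% NA_character_,
        pattern = r$pattern %||% NA_character_,
        feature = r$feature %||% NA_character_,
        direction = r$direction %||% NA_character_,
        cutoff = as.numeric(r$cutoff %||% NA_real_)
      )
    })
  })
  new_registry(df)
}
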