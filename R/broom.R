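#' Tidy a fitted logic tree
#'
#' @param x A `logic_fit`.
#' @param ... Unused.
#' @return One row per leaf: `rule_id`, `rule_index`, `complement`.
#' @exportS3Method generics::tidy
tidy.logic_fit <- function(x, ...) {
  leaves <- tree_leaves(x$tree)
  tibble::tibble(rule_id = x$rule_ids[leaves$index],
                 rule_index = leaves$index,
                 complement = leaves$complement)
}

#' One-row summary of a fitted logic tree
#'
#' @param x A `logic_fit`.
#' @param ... Unused.
#' @return One-row tibble: score, leaf count, move-acceptance count,
#'   iterations run, method and expression.
#' @exportS3Method generics::glance
glance.logic_fit <- function(x, ...) {
  tibble::tibble(
    score = x$score,
    n_leaves = tree_leaf_count(x$tree),
    n_accepted = x$n_accepted,
    n_iterations = length(x$trace),
    method = x$config$method,
    w_neg = x$config$weights$w_neg,
    expression = tree_to_expression(x$tree, x$rule_ids)
  )
}

#' Tidy a set of fitted target models
#'
#' @param x A `harmonizr_models` object.
#' @param ... Unused.
#' @return One row per fitted target: the [glance.logic_fit()] columns plus
#'   `target_name`.
#' @exportS3Method generics::tidy
tidy.harmonizr_models <- function(x, ...) {
  purrr::map_dfr(names(x), function(tn) {
    dplyr::mutate(glance(x[[tn]]), target_name = tn, .before = 1)
  })
}
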