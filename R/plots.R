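#' Plot the annealing score trace of a fitted logic tree
#'
#' Current score per iteration with the running best overlaid; the long
#' flat stretches late in the run are the signature of the decayed
#' transition probability.
#'
#' @param object A `logic_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.logic_fit <- function(object, ...) {
  df <- tibble::tibble(iteration = seq_along(object$trace),
                       score = object$trace,
                       best = cummin(object$trace))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$score), colour = "grey60") +
    ggplot2::geom_line(ggplot2::aes(y = .data$best), colour = "#2166ac") +
    ggplot2::labs(x = "iteration", y = "weighted score",
                  title = "Simulated-annealing score trace") +
    ggplot2::theme_minimal()
}

#' Main-effect plot of a tuning design
#'
#' Mean pooled sensitivity and specificity per level of each tuning factor,
#' the one-dimensional summary of the factorial tuning study.
#'
#' @param object A `design_results` tibble from [tune_design()].
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.design_results <- function(object, ...) {
  long <- object |>
    dplyr::select("method", "w_neg", "treesize", "minmass",
                  "sensitivity", "specificity") |>
    dplyr::mutate(dplyr::across(c("method", "w_neg", "treesize", "minmass"),
                                as.character)) |>
    tidyr::pivot_longer(c("method", "w_neg", "treesize", "minmass"),
                        names_to = "factor", values_to = "level") |>
    tidyr::pivot_longer(c("sensitivity", "specificity"),
                        names_to = "metric", values_to = "value") |>
    dplyr::group_by(.data$factor, .data$level, .data$metric) |>
    dplyr::summarise(value = mean(.data$value, na.rm = TRUE),
                     .groups = "drop")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$level, y = .data$value,
                                     colour = .data$metric,
                                     group = .data$metric)) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~factor, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "pooled value",
                  title = "Tuning-factor main effects") +
    ggplot2::theme_minimal()
}

#' Per-target performance dot plot
#'
#' Sensitivity, specificity, PPV and NPV per target in both samples; the
#' characteristic picture is high NPV throughout with widely scattered PPV.
#'
#' @param object A `performance_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.performance_report <- function(object, ...) {
  long <- tibble::as_tibble(object) |>
    dplyr::filter(.data$target != "Average") |>
    tidyr::pivot_longer(-dplyr::any_of(c("target", "unit")),
                        names_to = c("sample", "metric"), names_sep = "_",
                        values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value, y = .data$target,
                                     colour = .data$sample)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::facet_wrap(~metric, nrow = 1) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Per-target allocation performance") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_text(size = 6))
}
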