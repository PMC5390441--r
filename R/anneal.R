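#' Case/control weights of the evaluation function
#'
#' The annealing score is a weighted least-squares loss; for 0/1 outcomes it
#' reduces to a weighted misclassification count. To buy sensitivity on a
#' problem with very few positives (at most one matching variable per target
#' per dataset), the positives carry almost all the weight: the operating
#' weights 0.9995 / 0.0005 charge a missed match 1999 times as much as a
#' false alarm.
#'
#' @param w_neg Weight of the negatives, in (0, 1). `w_pos` is `1 - w_neg`.
#' @return List with `w_pos` and `w_neg`.
#' @export
score_weights <- function(w_neg = 5e-4) {
  stopifnot(w_neg > 0, w_neg < 1)
  list(w_pos = 1 - w_neg, w_neg = w_neg)
}

#' Weighted misclassification score
#'
#' @param predictions,labels Binary vectors of equal length.
#' @param weights Weights from [score_weights()].
#' @return Sum of `w_pos` over misclassified positives plus `w_neg` over
#'   misclassified negatives; 0 for perfect predictions.
#' @export
#' @examples
#' score_classification(c(0, 1, 0), c(1, 0, 0), score_weights(5e-4))
score_classification <- function(predictions, labels, weights = score_weights()) {
  if (length(predictions) != length(labels)) {
    abort("predictions and labels differ in length")
  }
  p <- as.integer(predictions)
  y <- as.integer(labels)
  weights$w_pos * sum(y == 1 & p == 0) + weights$w_neg * sum(y == 0 & p == 1)
}

#' Weighted deviance of a one-covariate logistic fit
#'
#' Fits `P(y = 1) = plogis(a + b * x)` for a binary covariate `x` (the tree
#' output) by weighted maximum likelihood with per-observation weights
#' `w_pos` / `w_neg`, and returns the weighted deviance. For a binary
#' covariate the weighted MLE has the closed form of group-wise weighted
#' outcome means; fitted linear predictors are capped at +/-30 so perfectly
#' separating trees return a near-zero (not degenerate) deviance. A constant
#' covariate yields the intercept-only weighted deviance.
#'
#' @param tree_outputs Binary vector of tree evaluations.
#' @param labels Binary labels; both classes must be present.
#' @param weights Weights from [score_weights()].
#' @return The weighted deviance (non-negative scalar).
#' @export
score_logistic <- function(tree_outputs, labels, weights = score_weights()) {
  if (length(tree_outputs) != length(labels)) {
    abort("tree_outputs and labels differ in length")
  }
  x <- as.integer(tree_outputs)
  y <- as.integer(labels)
  if (length(unique(y)) < 2) abort("labels must contain both classes")
  w <- ifelse(y == 1, weights$w_pos, weights$w_neg)
  cap <- function(p) plogis(pmin(pmax(qlogis(p), -30), 30))
  fitted <- numeric(length(y))
  for (g in unique(x)) {
    sel <- x == g
    fitted[sel] <- cap(sum(w[sel] * y[sel]) / sum(w[sel]))
  }
  -2 * sum(w * (y * log(fitted) + (1 - y) * log(1 - fitted)))
}

#' Annealing configuration
#'
#' @param method Scoring method: weighted misclassification
#'   (`"classification"`) or weighted logistic deviance (`"logistic"`).
#' @param weights Case/control weights, see [score_weights()].
#' @param treesize Maximum number of leaves of a candidate tree.
#' @param minmass Minimum number of training instances on which a candidate
#'   tree must evaluate true; violating proposals are rejected.
#' @param p_start,p_end Start and end acceptance probability for
#'   score-worsening moves; the probability decays geometrically from
#'   `p_start` to `p_end` over the run.
#' @param n_iterations Number of annealing iterations.
#' @param seed Integer seed; fitting is bit-reproducible given the seed.
#' @return An `anneal_config` list.
#' @export
anneal_config <- function(method = c("classification", "logistic"),
                          weights = score_weights(), treesize = 5L,
                          minmass = 4L, p_start = 0.1, p_end = 1e-4,
                          n_iterations = 50000L, seed = 1L) {
  method <- match.arg(method)
  stopifnot(treesize >= 1, minmass >= 0, p_start > p_end, p_end > 0)
  structure(
    list(method = method, weights = weights, treesize = as.integer(treesize),
         minmass = as.integer(minmass), p_start = p_start, p_end = p_end,
         n_iterations = as.integer(n_iterations), seed = as.integer(seed)),
    class = "anneal_config"
  )
}

config_score_fun <- function(config) {
  if (config$method == "classification") {
    function(pred, labels) score_classification(pred, labels, config$weights)
  } else {
    function(pred, labels) score_logistic(pred, labels, config$weights)
  }
}

#' Fit one logic tree by simulated annealing
#'
#' Starting from a uniformly random single leaf, repeatedly proposes one of
#' the six elementary tree moves (see [propose_move()]). Score-improving (or
#' equal) moves are always accepted; score-worsening moves are accepted with
#' a transition probability that decays geometrically from `p_start` to
#' `p_end` over the run. Proposals exceeding `treesize` leaves, or
#' predicting positive on fewer than `minmass` training instances, are
#' rejected outright. The best-scoring constraint-satisfying tree seen
#' anywhere in the run is returned (ties: first encountered wins). The run
#' stops early once a zero-score tree has been found, since the score is
#' bounded below by zero.
#'
#' @param rule_matrix 0/1 matrix, instances x rules; column names are rule
#'   ids.
#' @param labels Binary vector, one label per instance; at least one
#'   positive is required.
#' @param config An [anneal_config()].
#' @return A `logic_fit` object: `tree`, `score`, `trace` (current score per
#'   iteration), `n_accepted`, `rule_ids`, `config`.
#' @export
anneal <- function(rule_matrix, labels, config = anneal_config()) {
  stopifnot(is.matrix(rule_matrix))
  labels <- as.integer(labels)
  if (length(labels) != nrow(rule_matrix)) {
    abort("labels must have one element per rule_matrix row")
  }
  if (sum(labels == 1) == 0) abort("target unlearnable: no positive labels")
  if (config$n_iterations < 1) abort("n_iterations must be >= 1")
  n_rules <- ncol(rule_matrix)
  score_fun <- config_score_fun(config)
  m <- rule_matrix > 0
  n_iter <- config$n_iterations
  # geometric decay of the transition probability for worsening moves
  p_sched <- if (n_iter == 1) config$p_end else {
    config$p_start * (config$p_end / config$p_start)^((seq_len(n_iter) - 1) / (n_iter - 1))
  }

  withr::with_seed(config$seed, {
    current <- logic_leaf(sample.int(n_rules, 1))
    current_pred <- eval_node(current, m)
    current_score <- score_fun(current_pred, labels)
    current_feasible <- sum(current_pred) >= config$minmass
    best <- NULL
    best_score <- Inf
    n_accepted <- 0L
    trace <- numeric(n_iter)
    if (current_feasible) {
      best <- current
      best_score <- current_score
    }
    for (t in seq_len(n_iter)) {
      if (best_score <= 0) {
        trace <- trace[seq_len(t - 1)]
        break
      }
      prop <- propose_move(current, n_rules)
      reject <- tree_leaf_count(prop) > config$treesize
      if (!reject) {
        prop_pred <- eval_node(prop, m)
        prop_feasible <- sum(prop_pred) >= config$minmass
        # a feasible chain never steps back into infeasibility
        reject <- !prop_feasible && current_feasible
      }
      if (!reject) {
        prop_score <- score_fun(prop_pred, labels)
        accept <- prop_score <= current_score || runif(1) < p_sched[t]
        if (accept) {
          current <- prop
          current_pred <- prop_pred
          current_score <- prop_score
          current_feasible <- prop_feasible
          n_accepted <- n_accepted + 1L
          if (prop_feasible && prop_score < best_score) {
            best <- prop
            best_score <- prop_score
          }
        }
      }
      trace[t] <- current_score
    }
    if (is.null(best)) {
      warn("no tree satisfied the minmass constraint; returning last state")
      best <- current
      best_score <- current_score
    }
    structure(
      list(tree = best, score = best_score, trace = trace,
           n_accepted = n_accepted,
           rule_ids = colnames(rule_matrix) %||% paste0("R", seq_len(n_rules)),
           config = config),
      class = "logic_fit"
    )
  })
}

#' @export
print.logic_fit <- function(x, ...) {
  cat("<logic_fit>\n")
  cat("  expression: ", tree_to_expression(x$tree, x$rule_ids), "\n", sep = "")
  cat("  score: ", format(x$score), " (", x$config$method, ", ",
      length(x$trace), " iterations, ", x$n_accepted, " accepted moves)\n",
      sep = "")
  invisible(x)
}

#' Predict with a fitted logic tree
#'
#' @param object A `logic_fit`.
#' @param rule_matrix 0/1 matrix with the same rule columns used in fitting.
#' @param ... Unused.
#' @return Logical vector of tree evaluations.
#' @export
predict.logic_fit <- function(object, rule_matrix, ...) {
  evaluate_tree(object$tree, rule_matrix > 0)
}
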