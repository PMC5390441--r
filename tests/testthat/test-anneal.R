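test_that("classification score is the weighted misclassification count", {
  w <- score_weights(5e-4)
  expect_equal(score_classification(c(1, 0, 1), c(1, 0, 1), w), 0)
  expect_equal(score_classification(0, 1, w), 0.9995)
  expect_equal(score_classification(c(0, 1, 0), c(1, 0, 0), w), 1.0000)
  expect_error(score_classification(c(1, 0), c(1)), "length")
  expect_error(score_weights(0), "w_neg")

  # monotone in each misclassification count separately
  base <- score_classification(c(0, 1), c(1, 0), w)
  expect_gt(score_classification(c(0, 0, 1), c(1, 1, 0), w), base)
  expect_gt(score_classification(c(0, 1, 1), c(1, 0, 0), w), base)
})

test_that("a false negative costs 1999 times a false positive at the operating weights", {
  w <- score_weights(5e-4)
  fn_cost <- score_classification(0, 1, w)
  fp_cost <- score_classification(1, 0, w)
  expect_equal(fn_cost / fp_cost, 1999)
})

test_that("logistic score matches closed forms and a grid-search oracle", {
  w <- score_weights(0.5)
  # constant covariate, balanced labels, equal weights: intercept-only
  # deviance with p-hat = 0.5, i.e. -2 * sum(w * log(0.5))
  expect_equal(score_logistic(rep(0, 10), rep(c(0, 1), 5), w),
               -2 * 10 * 0.5 * log(0.5))
  # perfect separation: far below the intercept-only deviance
  sep <- score_logistic(c(0, 0, 0, 1, 1), c(0, 0, 0, 1, 1), w)
  null_dev <- score_logistic(rep(0, 5), c(0, 0, 0, 1, 1), w)
  expect_lt(sep, 1e-3 * null_dev)
  expect_error(score_logistic(c(0, 1), c(1, 1), w), "both classes")

  withr::with_seed(41, {
    x <- rbinom(40, 1, 0.5)
    y <- as.integer(runif(40) < plogis(-1 + 2 * x))
    ww <- score_weights(0.2)
    wv <- ifelse(y == 1, ww$w_pos, ww$w_neg)
    dev <- function(a, b) {
      p <- plogis(a + b * x)
      -2 * sum(wv * (y * log(p) + (1 - y) * log(1 - p)))
    }
    grid_best <- min(outer(seq(-6, 6, 0.02), seq(-12, 12, 0.02), Vectorize(dev)))
    expect_equal(score_logistic(x, y, ww), grid_best, tolerance = 1e-4)
  })
})

planted_instances <- function(n = 250, n_rules = 8, seed = 42,
                              f = function(X) X[, 1] & X[, 2]) {
  withr::with_seed(seed, {
    X <- matrix(rbinom(n * n_rules, 1, 0.4), n, n_rules,
                dimnames = list(NULL, paste0("r", seq_len(n_rules))))
    list(X = X, y = as.integer(f(X)))
  })
}

test_that("annealing recovers a planted noiseless tree exactly", {
  d <- planted_instances()
  fit <- anneal(d$X, d$y, anneal_config(n_iterations = 3000, minmass = 4,
                                        seed = 7))
  expect_equal(fit$score, 0)
  expect_lte(tree_leaf_count(fit$tree), 5)
  expect_equal(unname(predict(fit, d$X)), d$y == 1)
  # an exhaustive check that score 0 is attainable with <= 2 leaves backs
  # the planted construction
  zero_exists <- any(vapply(enumerate_small_trees(2), function(t) {
    all((evaluate_tree(t, d$X[, 1:2, drop = FALSE])) == (d$y == 1))
  }, logical(1)))
  expect_true(zero_exists)
})

test_that("annealing is deterministic given the seed", {
  d <- planted_instances(f = function(X) X[, 1] | (X[, 3] & X[, 5]))
  cfg <- anneal_config(n_iterations = 1500, minmass = 4, seed = 99)
  f1 <- anneal(d$X, d$y, cfg)
  f2 <- anneal(d$X, d$y, cfg)
  expect_identical(f1, f2)
})

test_that("annealing validates its inputs", {
  d <- planted_instances()
  expect_error(anneal(d$X, rep(0, nrow(d$X))), "no positive")
  expect_error(anneal(d$X, d$y, anneal_config(n_iterations = 0)),
               "n_iterations")
  expect_error(anneal(d$X, d$y[-1]), "one element per")
})

test_that("labels independent of the rules cannot be beaten meaningfully", {
  withr::with_seed(43, {
    X <- matrix(rbinom(300 * 6, 1, 0.5), 300, 6)
    y <- rbinom(300, 1, 0.3)
    w <- score_weights(0.5)
    fit <- anneal(X, y, anneal_config(weights = w, n_iterations = 2000,
                                      minmass = 0, seed = 3))
    best_constant <- min(score_classification(rep(0, 300), y, w),
                         score_classification(rep(1, 300), y, w))
    # within sampling noise a tree can exploit chance associations, but not
    # by much; allow 20% slack below the best constant predictor
    expect_gte(fit$score, 0.8 * best_constant)
  })
})

test_that("best score is non-increasing in the iteration budget (same seed)", {
  withr::with_seed(44, {
    X <- matrix(rbinom(200 * 6, 1, 0.5), 200, 6)
    y <- rbinom(200, 1, 0.25)  # unlearnable: scores stay positive
  })
  scores <- vapply(c(50, 200, 800, 2000), function(it) {
    anneal(X, y, anneal_config(n_iterations = it, minmass = 0, seed = 5))$score
  }, numeric(1))
  expect_true(all(diff(scores) <= 1e-12))
})

test_that("treesize and minmass constraints hold on the fitted tree", {
  d <- planted_instances(f = function(X) X[, 1] | X[, 2] | X[, 3])
  for (ts in c(2L, 5L)) {
    fit <- anneal(d$X, d$y, anneal_config(treesize = ts, minmass = 10,
                                          n_iterations = 1500, seed = 2))
    expect_lte(tree_leaf_count(fit$tree), ts)
    expect_gte(sum(predict(fit, d$X)), 10)
  }
})

test_that("the score trace caps the reported best and fits the run length", {
  d <- planted_instances(f = function(X) X[, 1] & X[, 2] & X[, 3])
  fit <- anneal(d$X, d$y, anneal_config(n_iterations = 400, minmass = 0,
                                        seed = 11))
  expect_lte(fit$score, min(fit$trace))
  expect_lte(length(fit$trace), 400)
  expect_s3_class(glance(fit), "tbl_df")
  expect_equal(glance(fit)$n_leaves, tree_leaf_count(fit$tree))
  td <- tidy(fit)
  expect_equal(nrow(td), tree_leaf_count(fit$tree))
  expect_true(all(td$rule_id %in% colnames(d$X)))
})
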