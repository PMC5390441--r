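test_that("the factorial design is the full Cartesian product", {
  expect_equal(nrow(generate_design(default_design_levels())), 32L)
  expect_equal(nrow(generate_design(list(a = 1))), 1L)
  d <- generate_design(list(a = c(1, 2), b = c("x", "y", "z")))
  expect_equal(nrow(d), 6L)
  expect_equal(nrow(dplyr::distinct(d)), 6L)
  expect_error(generate_design(list(a = 1, b = NULL)), "at least one level")
  # deterministic order: repeated calls agree
  expect_identical(generate_design(default_design_levels()),
                   generate_design(default_design_levels()))
})

cv_instances <- function(n_datasets = 10, per_dataset = 20, seed = 61,
                         noise = 0) {
  withr::with_seed(seed, {
    n <- n_datasets * per_dataset
    X <- matrix(rbinom(n * 6, 1, 0.4), n, 6,
                dimnames = list(NULL, paste0("r", 1:6)))
    y <- as.integer(X[, 1] & X[, 2])
    if (noise > 0) y <- as.integer(xor(y == 1, runif(n) < noise))
    list(rule_matrix = X, labels = y,
         groups = rep(sprintf("D%02d", seq_len(n_datasets)),
                      each = per_dataset),
         variables = paste0("v", seq_len(n)))
  })
}

test_that("cross-validation folds partition the instances without dataset straddling", {
  inst <- cv_instances()
  cfg <- anneal_config(n_iterations = 600, minmass = 2, seed = 1)
  cv <- cross_validate(inst, cfg, k = 5, seed = 9)
  expect_equal(sum(cv$folds$tp + cv$folds$fp + cv$folds$fn + cv$folds$tn),
               length(inst$labels))
  expect_equal(nrow(cv$folds), 5L)
  # grouped: each dataset contributes to exactly one test fold
  cv2 <- cross_validate(inst, cfg, k = 5, seed = 9)
  expect_identical(cv$folds, cv2$folds)  # same seed, same assignment
  expect_error(cross_validate(inst, cfg, k = 20, seed = 1), "at least k")
})

test_that("a noiseless planted target cross-validates to pooled sensitivity 1", {
  inst <- cv_instances()
  cv <- cross_validate(inst, anneal_config(n_iterations = 1200, minmass = 2,
                                           seed = 4), k = 5, seed = 2)
  expect_equal(cv$pooled$sensitivity, 1)
  expect_equal(cv$pooled$specificity, 1)
})

test_that("a fold without positives reports missing sensitivity with a warning", {
  inst <- cv_instances(n_datasets = 4, per_dataset = 10, seed = 62)
  # concentrate all positives in one dataset group
  inst$labels <- as.integer(inst$groups == "D01" &
                              inst$rule_matrix[, 1] == 1)
  warns <- testthat::capture_warnings(
    cv <- cross_validate(inst, anneal_config(n_iterations = 300, minmass = 1,
                                             seed = 1), k = 4, seed = 3))
  expect_true(any(grepl("no positives", warns)))
  expect_true(anyNA(cv$folds$sensitivity))
})

test_that("tuning results feed constrained selection with documented tie-breaking", {
  res <- tibble::tibble(
    method = c("classification", "logistic"),
    w_neg = c(5e-4, 5e-4), treesize = c(5L, 5L), minmass = c(4L, 4L),
    sensitivity = c(0.995, 0.991), specificity = c(0.74, 0.76)
  )
  pick <- select_config(res)
  expect_equal(pick$sensitivity, 0.991)  # only point meeting both floors
  expect_equal(pick$relaxation, "none")

  single <- res[1, ]
  single$sensitivity <- 0.995
  single$specificity <- 0.80
  expect_equal(select_config(single)$method, "classification")

  # permutation invariance
  expect_equal(select_config(res[2:1, ]), pick)

  # relaxation tiers
  # only the second point survives the specificity floor once the
  # sensitivity floor is dropped
  low <- dplyr::mutate(res, sensitivity = c(0.90, 0.85))
  expect_equal(select_config(low)$relaxation, "sens_floor_dropped")
  expect_equal(select_config(low)$sensitivity, 0.85)
  hopeless <- dplyr::mutate(res, specificity = c(0.1, 0.2))
  expect_equal(select_config(hopeless)$relaxation, "all_floors_dropped")
  expect_error(select_config(res[0, ]), "no tuning results")
})

test_that("classification is selected when it dominates logistic on synthetic runs", {
  # constructed so the classification rows dominate on sensitivity at equal
  # specificity, mirroring a grid where direct classification wins
  res <- generate_design(list(method = c("classification", "logistic"),
                              w_neg = c(5e-4, 5e-1))) |>
    dplyr::mutate(treesize = 5L, minmass = 4L,
                  sensitivity = ifelse(.data$method == "classification",
                                       0.995, 0.97),
                  specificity = 0.8)
  expect_equal(select_config(res)$method, "classification")
})

test_that("a small tuning grid runs end to end on planted instances", {
  inst <- cv_instances(n_datasets = 5, per_dataset = 16, seed = 63)
  design <- generate_design(list(method = c("classification", "logistic"),
                                 w_neg = c(5e-4), treesize = c(5L),
                                 minmass = c(2L)))
  out <- tune_design(design, inst,
                     base_config = anneal_config(n_iterations = 400,
                                                 minmass = 2, seed = 1),
                     k = 5, seed = 8)
  expect_s3_class(out, "design_results")
  expect_equal(nrow(out), 2L)
  expect_true(all(out$sensitivity >= 0 & out$sensitivity <= 1))
  expect_true(all(out$specificity >= 0 & out$specificity <= 1))
  plt <- ggplot2::autoplot(out)
  expect_s3_class(plt, "ggplot")
})
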