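meta_row <- function(...) {
  defaults <- list(name = "v", label = NA_character_, dtype = "number",
                   scale = "ratio", n_values = 10L, prop_most_frequent = 0.2,
                   median = NA_real_, iqr = NA_real_, n_nonmissing = 100L)
  args <- utils::modifyList(defaults, list(...))
  tibble::as_tibble(args)
}

test_that("rule evaluation is total and matches the documented semantics", {
  m <- meta_row(name = "serum_cholesterol_mgdl", median = 121)
  expect_true(evaluate_rule(rule("r", "name_contains", pattern = "cholesterol"), m))
  expect_true(evaluate_rule(rule("r", "name_contains", pattern = "CHOLesterol"), m))
  expect_false(evaluate_rule(rule("r", "name_contains", pattern = "glucose"), m))

  thr <- rule("r", "threshold", feature = "median", direction = "gt", cutoff = 94)
  expect_true(evaluate_rule(thr, meta_row(median = 121)))
  expect_false(evaluate_rule(thr, meta_row(median = 80)))
  expect_false(evaluate_rule(thr, meta_row(median = 94)))
  # absent feature (string-typed variable): false, never NA
  expect_false(evaluate_rule(thr, meta_row(dtype = "string")))
  # absent label: false
  expect_false(evaluate_rule(rule("r", "label_contains", pattern = "x"), m))
  expect_true(evaluate_rule(rule("r", "label_contains", pattern = "blood"),
                            meta_row(label = "Systolic Blood Pressure")))
  expect_true(evaluate_rule(rule("r", "dtype_is", pattern = "number"), m))
  expect_false(evaluate_rule(rule("r", "scale_is", pattern = "ordinal"), m))
})

test_that("rule constructor enforces the kind/field pairing", {
  expect_error(rule("r", "threshold", pattern = "x"), "threshold")
  expect_error(rule("r", "name_contains", cutoff = 1), "pattern")
  expect_error(rule("r", "threshold", feature = "median", direction = "gt",
                    cutoff = 1, pattern = "x"), "threshold")
})

test_that("evaluate_ruleset produces the leaf-input row in rule order", {
  registry <- dplyr::bind_rows(
    dplyr::mutate(rule("r1", "name_contains", pattern = "age"),
                  target_name = "Age", unit = "years", .before = 1),
    dplyr::mutate(rule("r2", "dtype_is", pattern = "number"),
                  target_name = "Age", unit = "years", .before = 1)
  )
  m1 <- meta_row(name = "AGE")
  m2 <- meta_row(name = "sex", dtype = "string")
  expect_equal(as.vector(evaluate_ruleset(registry, "Age", m1)), c(1L, 1L))
  expect_equal(as.vector(evaluate_ruleset(registry, "Age", m2)), c(0L, 0L))
  both <- evaluate_ruleset(registry, "Age", dplyr::bind_rows(m1, m2))
  expect_equal(dim(both), c(2L, 2L))
  expect_equal(colnames(both), c("r1", "r2"))
  expect_error(evaluate_ruleset(registry, "Nope", m1), "unknown target")
})

test_that("optimize_cutoff maximizes sensitivity + specificity over midpoints", {
  res <- optimize_cutoff(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1), "gt")
  expect_equal(res$cutoff, 6.5)
  expect_equal(res$sensitivity, 1)
  expect_equal(res$specificity, 1)

  # ties between cutoffs 1.5 and 4.5 at sens+spec = 1.5: smallest wins
  res2 <- optimize_cutoff(c(1, 4, 2, 5), c(0, 0, 1, 1), "gt")
  expect_equal(res2$cutoff, 1.5)
  expect_equal(res2$sensitivity + res2$specificity, 1.5)

  res3 <- optimize_cutoff(c(3, 7), c(0, 1), "gt")
  expect_equal(res3$sensitivity, 1)
  expect_equal(res3$specificity, 1)

  expect_error(optimize_cutoff(c(1, 2), c(1, 1), "gt"), "uncalibratable")
})

test_that("optimize_cutoff agrees with the exhaustive oracle and is permutation-invariant", {
  withr::with_seed(11, {
    for (rep in 1:60) {
      n <- sample(3:12, 1)
      v <- round(runif(n, 0, 10), 1)
      y <- rbinom(n, 1, 0.4)
      if (length(unique(y)) < 2) next
      direction <- sample(c("gt", "lt"), 1)
      res <- optimize_cutoff(v, y, direction)
      oracle <- cutoff_oracle(v, y, direction)
      expect_equal(res$sensitivity + res$specificity, oracle$obj,
                   tolerance = 1e-12)
      perm <- sample.int(n)
      expect_equal(optimize_cutoff(v[perm], y[perm], direction), res)
    }
  })
})

test_that("raising all positive values cannot hurt the optimum for direction gt", {
  withr::with_seed(12, {
    for (rep in 1:20) {
      n <- 10
      v <- round(runif(n, 0, 10), 1)
      y <- c(1, 1, rbinom(n - 2, 1, 0.3))
      base <- optimize_cutoff(v, y, "gt")
      v2 <- v + ifelse(y == 1, runif(n, 0, 5), 0)
      shifted <- optimize_cutoff(v2, y, "gt")
      expect_gte(shifted$sensitivity + shifted$specificity,
                 base$sensitivity + base$specificity - 1e-12)
    }
  })
})

test_that("the packaged registry round-trips through YAML and validates", {
  registry <- default_registry()
  targets <- registry_targets(registry)
  expect_equal(nrow(targets), 41L)
  expect_true(all(targets$n_rules >= 4))
  expect_true("Systolic blood pressure" %in% targets$target_name)
  expect_equal(targets$unit[targets$target_name == "Systolic blood pressure"],
               "mmHg")

  path <- withr::local_tempfile(fileext = ".yaml")
  write_registry(registry, path)
  expect_equal(read_registry(path), registry)

  # registry errors are reported with the offending entries
  expect_error(read_registry(withr::local_tempfile(fileext = ".yaml")),
               "not found")
  bad <- registry
  bad$kind[1] <- "regex_match"
  path2 <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(schema_version = 1, targets = list()), path2)
  expect_error(read_registry(path2), "no targets|missing columns")
  expect_error(harmonizr:::new_registry(bad), "unknown rule kind.*regex_match")
  dup <- dplyr::bind_rows(registry, registry[1, ])
  expect_error(harmonizr:::new_registry(dup), "duplicate rule ids")
})

test_that("calibrate_registry re-optimizes threshold cutoffs from gold labels", {
  registry <- dplyr::bind_rows(
    dplyr::mutate(rule("name", "name_contains", pattern = "press"),
                  target_name = "SBP", unit = "mmHg", .before = 1),
    dplyr::mutate(rule("med", "threshold", feature = "median",
                       direction = "gt", cutoff = 999),
                  target_name = "SBP", unit = "mmHg", .before = 1)
  )
  profiles <- dplyr::bind_rows(
    meta_row(name = "pressure", median = 130),
    meta_row(name = "pulse", median = 70),
    meta_row(name = "weight", median = 80)
  ) |>
    dplyr::mutate(dataset_id = "D1", .before = 1)
  gold <- tibble::tibble(dataset_id = "D1", source_variable = "pressure",
                         target_name = "SBP")
  out <- calibrate_registry(registry, profiles, gold)
  expect_equal(out$cutoff[out$rule_id == "med"], 105)  # midpoint of 80 and 130
  expect_true(evaluate_rule(out[out$rule_id == "med", ],
                            profiles[profiles$name == "pressure", ]))
})
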