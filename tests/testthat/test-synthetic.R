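test_that("generated cohorts have the promised shape and ledger", {
  spec <- cohort_spec(n_participants = 120, n_noise_variables = 50,
                      targets_present = c("Age", "Sex"), seed = 3)
  cohort <- generate_cohort(spec)
  expect_equal(ncol(cohort$data), 52L)
  expect_equal(nrow(cohort$data), 120L)
  expect_equal(nrow(cohort$truth), 2L)
  expect_setequal(cohort$truth$target_name, c("Age", "Sex"))
  expect_true(all(cohort$truth$column_name %in% names(cohort$data)))
  expect_equal(nrow(cohort$labels), 52L)

  expect_error(
    generate_cohort(cohort_spec(targets_present = "Shoe size")),
    "unknown targets")
})

test_that("generation is deterministic given the seed, byte for byte", {
  spec <- cohort_spec(n_participants = 60, n_noise_variables = 20,
                      targets_present = c("Age", "Cholesterol"), seed = 17)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(generate_cohort(spec)$data, f1, row.names = FALSE)
  write.csv(generate_cohort(spec)$data, f2, row.names = FALSE)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("a planted systolic blood pressure column has median above the textbook cutoff", {
  hits <- vapply(1:40, function(s) {
    cohort <- generate_cohort(cohort_spec(
      n_participants = 150, n_noise_variables = 0,
      targets_present = "Systolic blood pressure", seed = s))
    prof <- profile_dataset(cohort$data, labels = cohort$labels)
    prof$median > 94
  }, logical(1))
  # Normal(130, 17): the sample median essentially never falls below 94
  expect_true(all(hits))
})

test_that("suites split construction/validation at the requested ratio", {
  base <- cohort_spec(n_participants = 50, n_noise_variables = 10,
                      targets_present = c("Age", "Sex"))
  suite <- generate_suite(7, preset = "easy", base_spec = base, seed = 5)
  expect_equal(sort(table(suite$manifest$use), decreasing = TRUE) |> unname() |>
                 as.integer(), c(4L, 3L))
  expect_equal(length(suite$datasets), 7L)
  # every gold mapping resolves against its dataset's header
  for (i in seq_len(nrow(suite$gold))) {
    ds <- suite$gold$dataset_id[i]
    expect_true(suite$gold$source_variable[i] %in%
                  names(suite$datasets[[ds]]$data))
  }
  # a 34-dataset suite splits 17/17
  big <- generate_suite(34, preset = "easy",
                        base_spec = cohort_spec(
                          n_participants = 30, n_noise_variables = 5,
                          targets_present = "Age"),
                        seed = 2)
  expect_equal(unname(table(big$manifest$use)["construction"]), 17L)
})

test_that("suite round trip: instance positives equal the ledger totals", {
  targets <- c("Age", "Sex", "Cholesterol", "Diabetes")
  base <- cohort_spec(n_participants = 80, n_noise_variables = 15,
                      targets_present = targets)
  suite <- generate_suite(4, preset = "easy", base_spec = base, seed = 9)
  registry <- default_registry()
  registry <- registry[registry$target_name %in% targets, ]
  profiles <- profile_suite(suite)
  inst <- build_instances(profiles, registry, suite$gold)
  for (tn in targets) {
    expect_equal(sum(inst[[tn]]$labels),
                 sum(suite$gold$target_name == tn))
    expect_equal(sum(inst[[tn]]$labels), length(suite$datasets))
  }
})

test_that("suites survive a disk round trip in the package formats", {
  base <- cohort_spec(n_participants = 40, n_noise_variables = 8,
                      targets_present = c("Age", "Sex"))
  suite <- generate_suite(3, preset = "easy", base_spec = base, seed = 13)
  dir <- withr::local_tempdir()
  write_suite(suite, dir)
  back <- read_suite(dir)
  expect_equal(back$manifest$dataset_id, suite$manifest$dataset_id)
  expect_equal(back$gold, suite$gold)
  expect_equal(names(back$datasets[["D01"]]$data),
               names(suite$datasets[["D01"]]$data))
  # values survive as text: profiling agrees
  p1 <- profile_dataset(suite$datasets[["D01"]]$data,
                        suite$datasets[["D01"]]$labels)
  p2 <- profile_dataset(back$datasets[["D01"]]$data,
                        back$datasets[["D01"]]$labels)
  expect_equal(p1, p2)
})

test_that("the hard preset plants adversarial shadows and drops labels", {
  base <- cohort_spec(n_participants = 60, n_noise_variables = 20,
                      targets_present = c("Age", "Cholesterol"))
  suite <- generate_suite(3, preset = "hard", base_spec = base, seed = 21)
  labels <- suite$datasets[["D01"]]$labels
  expect_true(anyNA(labels$label))
  # shadow columns carry the repeat-measurement label
  expect_true(any(grepl("repeat measurement", labels$label), na.rm = TRUE))
  # coded or abbreviated names, never the verbose ones
  expect_false("age_years" %in% names(suite$datasets[["D01"]]$data))
})
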