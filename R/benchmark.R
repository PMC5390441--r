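#' Representative target subset for desk-scale pipeline benchmarks
#'
#' Ten targets spanning the variable kinds the registry distinguishes:
#' conventional and SI continuous measurements, dichotomous flags, an
#' ordinal scale and a date, including the lexically entangled cholesterol
#' family.
#'
#' @return Character vector of target names.
#' @export
benchmark_targets <- function() {
  c("Age", "Sex", "Systolic blood pressure", "Cholesterol",
    "Cholesterol SI", "HDL cholesterol", "Diabetes", "Smoking status",
    "Ultrasound date", "Intima media thickness SI")
}

#' Run the full allocation pipeline on a synthetic suite
#'
#' The end-to-end benchmark: generates a suite under the given preset,
#' profiles construction and validation datasets, builds instances, fits one
#' tree per target on the construction sample, and evaluates on the
#' validation sample. On the `"easy"` preset this is the correctness gate
#' (the pipeline must identify every planted variable); on the `"hard"`
#' preset it reproduces the qualitative operating regime of heavily
#' class-weighted screening: near-complete sensitivity and NPV, but a PPV
#' far below either.
#'
#' @param preset `"easy"` or `"hard"`, see [generate_suite()].
#' @param n_datasets Number of cohorts in the suite.
#' @param targets Planted targets (default [benchmark_targets()]).
#' @param n_participants,n_noise_variables Base cohort dimensions (jittered
#'   per dataset).
#' @param config An [anneal_config()]; `minmass` should not exceed the
#'   number of construction datasets (one positive per dataset per target).
#' @param seed Master seed for suite generation.
#' @return List: `pooled` (validation-sample pooled metrics), `per_target`,
#'   `train_scores` (per-target best scores on the construction sample),
#'   `models`, `suite`.
#' @export
run_benchmark <- function(preset = c("easy", "hard"), n_datasets = 8L,
                          targets = benchmark_targets(),
                          n_participants = 300L, n_noise_variables = 40L,
                          config = anneal_config(n_iterations = 2500L,
                                                 minmass = 2L),
                          seed = 1L) {
  preset <- match.arg(preset)
  base <- cohort_spec(n_participants = n_participants,
                      n_noise_variables = n_noise_variables,
                      targets_present = targets)
  suite <- generate_suite(n_datasets, preset = preset, base_spec = base,
                          seed = seed)
  registry <- default_registry()
  registry <- registry[registry$target_name %in% targets, , drop = FALSE]
  con_ids <- suite$manifest$dataset_id[suite$manifest$use == "construction"]
  val_ids <- suite$manifest$dataset_id[suite$manifest$use == "validation"]
  prof_con <- profile_suite(suite, use = "construction")
  prof_val <- profile_suite(suite, use = "validation")
  inst <- build_instances(prof_con, registry,
                          suite$gold[suite$gold$dataset_id %in% con_ids, ])
  models <- fit_all_targets(inst, config)
  res <- evaluate_models(models, registry, prof_val,
                         suite$gold[suite$gold$dataset_id %in% val_ids, ])
  list(pooled = res$pooled, per_target = res$per_target,
       train_scores = vapply(models, function(m) m$score, numeric(1)),
       models = models, suite = suite)
}
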