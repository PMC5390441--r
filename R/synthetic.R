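#' Specification of one synthetic cohort dataset
#'
#' Describes a synthetic cohort emulating the inputs of a harmonization
#' project: a block of planted target variables with known ground truth plus
#' a block of noise variables, under a naming dialect. Defaults emulate a
#' mid-sized cohort export (500 participants, 60 noise variables, 2%
#' missingness); real acquisitions in this field range from roughly 100 to
#' 15,000 participants and from tens to a couple of thousand variables.
#'
#' @param n_participants Number of rows.
#' @param n_noise_variables Number of non-target columns (includes any
#'   adversarial decoys).
#' @param targets_present Target names planted in the dataset; must exist in
#'   the registry.
#' @param naming_dialect `"verbose"` (full descriptive names),
#'   `"abbreviated"` (short names with mechanical perturbations) or
#'   `"coded"` (opaque positional codes carrying no lexical signal).
#' @param missing_rate Fraction of cells set missing uniformly at random,
#'   in `[0, 1)`.
#' @param label_coverage Fraction of variables that get a label in the
#'   sidecar.
#' @param decoy_profile `"benign"` (noise variables lexically and
#'   numerically far from every target) or `"adversarial"` (near-miss names
#'   and one distribution-identical shadow per planted target).
#' @param seed Integer seed; generation is fully deterministic given it.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_participants = 500L, n_noise_variables = 60L,
                        targets_present = target_templates()$target_name,
                        naming_dialect = c("verbose", "abbreviated", "coded"),
                        missing_rate = 0.02, label_coverage = 1,
                        decoy_profile = c("benign", "adversarial"),
                        seed = 1L) {
  stopifnot(missing_rate >= 0, missing_rate < 1,
            label_coverage >= 0, label_coverage <= 1)
  structure(
    list(n_participants = as.integer(n_participants),
         n_noise_variables = as.integer(n_noise_variables),
         targets_present = targets_present,
         naming_dialect = match.arg(naming_dialect),
         missing_rate = missing_rate,
         label_coverage = label_coverage,
         decoy_profile = match.arg(decoy_profile),
         seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

draw_template_values <- function(t, n) {
  switch(t$vkind,
    continuous = {
      if (t$dist == "lnorm") round(rlnorm(n, t$mu, t$sigma), 4)
      else round(rnorm(n, t$mu, t$sigma), 4)
    },
    binary = rbinom(n, 1, t$p),
    ordinal = sample.int(t$n_levels, n, replace = TRUE),
    nominal = sample(c("caucasian", "asian", "african", "hispanic", "other"),
                     n, replace = TRUE),
    date = format(as.Date("2000-01-01") + sample.int(4000, n, replace = TRUE),
                  "%Y-%m-%d")
  )
}

# Benign noise templates: lexically unrelated to every target synonym and
# numerically far from every authored median band.
benign_noise_pool <- function() {
  list(
    list(name = "participant_id", gen = function(n) sample(100000:999999, n)),
    list(name = "center_code", gen = function(n) sample.int(9, n, TRUE)),
    list(name = "visit_number", gen = function(n) sample.int(4, n, TRUE)),
    list(name = "qc_flag", gen = function(n) rbinom(n, 1, 0.05)),
    list(name = "consent_given", gen = function(n) rbinom(n, 1, 0.97)),
    list(name = "fieldworker", gen = function(n)
      sample(c("fw_a", "fw_b", "fw_c", "fw_d"), n, TRUE)),
    list(name = "device_serial", gen = function(n)
      paste0("SN", sample(10000:99999, n, TRUE))),
    list(name = "room_assignment", gen = function(n) sample.int(6, n, TRUE)),
    list(name = "completeness_fraction", gen = function(n)
      round(runif(n, 0, 0.2), 4)),
    list(name = "batch_index", gen = function(n) sample(200:999, n, TRUE)),
    list(name = "questionnaire_version", gen = function(n)
      sample.int(3, n, TRUE)),
    list(name = "followup_flag", gen = function(n) rbinom(n, 1, 0.5))
  )
}

# Adversarial decoys: near-miss names sharing substrings with target
# synonyms, drawn over distributions inside the targets' plausible bands.
adversarial_noise_pool <- function() {
  list(
    list(name = "hdl_chol_ratio", gen = function(n) round(runif(n, 2, 8), 4)),
    list(name = "cholesterol_year", gen = function(n) sample(1990:2010, n, TRUE)),
    list(name = "age_at_event", gen = function(n) round(rnorm(n, 62, 9), 4)),
    list(name = "sexual_activity_score", gen = function(n) sample.int(5, n, TRUE)),
    list(name = "medication_count", gen = function(n) sample(0:12, n, TRUE)),
    list(name = "histology_code", gen = function(n) sample.int(9, n, TRUE)),
    list(name = "glucose_tolerance_class", gen = function(n) sample.int(3, n, TRUE)),
    list(name = "imt_reader_id", gen = function(n) sample.int(8, n, TRUE)),
    list(name = "packaging_batch", gen = function(n) sample(1:50, n, TRUE)),
    list(name = "diabetic_diet_flag", gen = function(n) rbinom(n, 1, 0.1)),
    list(name = "smokehouse_region", gen = function(n) sample.int(4, n, TRUE)),
    list(name = "education_of_parent", gen = function(n) sample.int(4, n, TRUE))
  )
}

dialect_name <- function(t, dialect, occupied) {
  base <- switch(dialect,
    verbose = t$vname,
    abbreviated = {
      suffix <- sample(c("", "_v1", "_bl", "2", "_x"), 1)
      caseify <- sample(c(identity, toupper), 1)[[1]]
      paste0(caseify(t$abbr), suffix)
    },
    coded = sprintf("var%04d", sample.int(9999, 1))
  )
  nm <- base
  k <- 1L
  while (nm %in% occupied) {
    k <- k + 1L
    nm <- paste0(base, "_", k)
  }
  nm
}

#' Generate one synthetic cohort with ground truth
#'
#' Draws the planted target columns from the per-target distribution
#' templates of [target_templates()] (chosen so the packaged rules are
#' informative: e.g. systolic blood pressure ~ Normal(130, 17) mmHg, sex as
#' a 0/1 dichotomous flag, SI and conventional lipid units on different
#' scales), fills the remaining columns from a decoy pool, applies the
#' naming dialect, the label sidecar coverage and uniform missingness, and
#' records every planted column in the ground-truth ledger.
#'
#' @param spec A [cohort_spec()].
#' @param registry Rule registry; `spec$targets_present` must be a subset of
#'   its targets.
#' @return List with `data` (tibble), `labels` (sidecar tibble `name`,
#'   `label`), and `truth` (ledger tibble `target_name`, `column_name`,
#'   `params`).
#' @export
generate_cohort <- function(spec, registry = default_registry()) {
  templates <- target_templates()
  unknown <- setdiff(spec$targets_present, registry$target_name)
  if (length(unknown) > 0) {
    abort(paste0("unknown targets: ", paste(unknown, collapse = ", ")))
  }
  templates <- templates[match(spec$targets_present, templates$target_name), ]
  withr::with_seed(spec$seed, {
    n <- spec$n_participants
    columns <- list()
    labels <- character()
    truth <- list()
    for (i in seq_len(nrow(templates))) {
      t <- templates[i, ]
      nm <- dialect_name(t, spec$naming_dialect, names(columns))
      columns[[nm]] <- draw_template_values(t, n)
      labels[nm] <- t$label
      truth[[length(truth) + 1]] <- tibble::tibble(
        target_name = t$target_name, column_name = nm,
        params = paste0(t$vkind, ifelse(t$vkind == "continuous",
                                        paste0("(", t$mu, ",", t$sigma, ")"),
                                        "")))
    }
    n_noise <- spec$n_noise_variables
    if (spec$decoy_profile == "adversarial") {
      # one distribution-identical shadow per planted target, within the
      # noise budget: the classic repeated-measurement column
      n_shadow <- min(nrow(templates), n_noise)
      for (i in seq_len(n_shadow)) {
        t <- templates[i, ]
        nm <- dialect_name(t, sample(c("abbreviated", "coded"), 1),
                           names(columns))
        columns[[nm]] <- draw_template_values(t, n)
        labels[nm] <- paste0(t$label, " (repeat measurement)")
      }
      n_noise <- n_noise - n_shadow
      pool <- c(adversarial_noise_pool(), benign_noise_pool())
    } else {
      pool <- benign_noise_pool()
    }
    for (j in seq_len(n_noise)) {
      d <- pool[[(j - 1L) %% length(pool) + 1L]]
      nm <- d$name
      k <- 1L
      while (nm %in% names(columns)) {
        k <- k + 1L
        nm <- paste0(d$name, "_", k)
      }
      columns[[nm]] <- d$gen(n)
      labels[nm] <- gsub("_", " ", nm)
    }
    data <- tibble::as_tibble(columns)
    if (spec$missing_rate > 0) {
      for (nm in names(data)) {
        miss <- runif(n) < spec$missing_rate
        if (any(miss)) data[[nm]][miss] <- NA
      }
    }
    sidecar <- tibble::tibble(name = names(data),
                              label = unname(labels[names(data)]))
    if (spec$label_coverage < 1) {
      drop <- runif(nrow(sidecar)) > spec$label_coverage
      sidecar$label[drop] <- NA_character_
    }
    list(data = data, labels = sidecar, truth = dplyr::bind_rows(truth))
  })
}

#' Generate a suite of heterogeneous synthetic cohorts
#'
#' Produces everything the allocation pipeline consumes: one dataset per
#' cohort (sizes and dialects jittered around `base_spec`), the gold-mapping
#' table derived from the ground-truth ledgers, and a manifest assigning
#' each dataset to the construction or validation sample at the given ratio
#' (floor/ceil rounding, random 1:1 assignment).
#'
#' The `"easy"` preset (verbose names, full labels, benign decoys, no
#' missingness) makes every target perfectly identifiable and serves as the
#' end-to-end correctness gate; the `"hard"` preset (abbreviated/coded
#' names, half-covered labels, adversarial decoys with one
#' distribution-identical shadow per target) emulates the regime where
#' positive predictions are frequently wrong while negative predictions
#' remain reliable.
#'
#' @param n_datasets Number of cohorts, at least 2.
#' @param preset `"easy"`, `"hard"`, or `NULL` to use `base_spec` as is.
#' @param base_spec Template [cohort_spec()].
#' @param split_ratio Fraction of datasets assigned to the construction
#'   sample.
#' @param seed Master seed; per-dataset seeds are derived from it.
#' @param registry Rule registry.
#' @return List with `datasets` (named list of [generate_cohort()] outputs),
#'   `gold` (tibble `dataset_id`, `source_variable`, `target_name`), and
#'   `manifest` (tibble `dataset_id`, `n_variables`, `n_participants`,
#'   `use`).
#' @export
generate_suite <- function(n_datasets = 6L, preset = c("easy", "hard"),
                           base_spec = cohort_spec(), split_ratio = 0.5,
                           seed = 1L, registry = default_registry()) {
  stopifnot(n_datasets >= 2)
  if (!is.null(preset)) {
    preset <- match.arg(preset)
    base_spec <- switch(preset,
      easy = modify_spec(base_spec, naming_dialect = "verbose",
                         missing_rate = 0, label_coverage = 1,
                         decoy_profile = "benign"),
      hard = modify_spec(base_spec, missing_rate = 0.05,
                         label_coverage = 0.5, decoy_profile = "adversarial")
    )
  }
  withr::with_seed(seed, {
    sizes <- round(base_spec$n_participants *
                     runif(n_datasets, 0.5, 2))
    noise <- round(base_spec$n_noise_variables *
                     runif(n_datasets, 0.7, 1.5))
    dialects <- if (!is.null(preset) && preset == "hard") {
      sample(c("abbreviated", "coded"), n_datasets, replace = TRUE)
    } else {
      rep(base_spec$naming_dialect, n_datasets)
    }
    n_con <- floor(n_datasets * split_ratio)
    use <- sample(c(rep("construction", n_con),
                    rep("validation", n_datasets - n_con)))
  })
  ids <- sprintf("D%02d", seq_len(n_datasets))
  datasets <- list()
  gold <- list()
  manifest <- list()
  for (i in seq_len(n_datasets)) {
    spec_i <- modify_spec(base_spec,
                          n_participants = sizes[i],
                          n_noise_variables = noise[i],
                          naming_dialect = dialects[i],
                          seed = derive_seed(seed, i))
    cohort <- generate_cohort(spec_i, registry)
    datasets[[ids[i]]] <- cohort
    gold[[i]] <- dplyr::mutate(
      cohort$truth[, c("column_name", "target_name")],
      dataset_id = ids[i], .before = 1) |>
      dplyr::rename(source_variable = "column_name")
    manifest[[i]] <- tibble::tibble(
      dataset_id = ids[i], n_variables = ncol(cohort$data),
      n_participants = nrow(cohort$data), use = use[i])
  }
  list(datasets = datasets, gold = dplyr::bind_rows(gold),
       manifest = dplyr::bind_rows(manifest))
}

modify_spec <- function(spec, ...) {
  changes <- list(...)
  for (nm in names(changes)) spec[[nm]] <- changes[[nm]]
  cohort_spec(n_participants = spec$n_participants,
              n_noise_variables = spec$n_noise_variables,
              targets_present = spec$targets_present,
              naming_dialect = spec$naming_dialect,
              missing_rate = spec$missing_rate,
              label_coverage = spec$label_coverage,
              decoy_profile = spec$decoy_profile,
              seed = spec$seed)
}

#' Profile every dataset of a suite
#'
#' Convenience wrapper: profiles each generated dataset with its label
#' sidecar and stacks the results with a `dataset_id` column, ready for
#' [build_instances()].
#'
#' @param suite Output of [generate_suite()].
#' @param use Restrict to manifest `use` values (e.g. `"construction"`);
#'   `NULL` profiles everything.
#' @return Tibble of profiles with a `dataset_id` column.
#' @export
profile_suite <- function(suite, use = NULL) {
  ids <- suite$manifest$dataset_id
  if (!is.null(use)) ids <- ids[suite$manifest$use %in% use]
  purrr::map_dfr(ids, function(ds) {
    cohort <- suite$datasets[[ds]]
    profile_dataset(cohort$data, labels = cohort$labels) |>
      dplyr::mutate(dataset_id = ds, .before = 1)
  })
}

#' Write a generated suite to disk in the package's CSV formats
#'
#' Emits `<id>.csv` and `<id>_labels.csv` per dataset plus `gold.csv` and
#' `manifest.csv`, exactly the formats the profiling and allocation
#' functions read back.
#'
#' @param suite Output of [generate_suite()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_suite <- function(suite, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (ds in names(suite$datasets)) {
    cohort <- suite$datasets[[ds]]
    write.csv(cohort$data, file.path(dir, paste0(ds, ".csv")),
              row.names = FALSE, na = "")
    write.csv(cohort$labels, file.path(dir, paste0(ds, "_labels.csv")),
              row.names = FALSE, na = "")
  }
  write.csv(suite$gold, file.path(dir, "gold.csv"), row.names = FALSE)
  write.csv(suite$manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(dir)
}
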