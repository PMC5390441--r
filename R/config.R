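config_defaults <- function() {
  list(
    method = "classification",
    w_neg = 5e-4,
    treesize = 5L,
    minmass = 4L,
    p_start = 0.1,
    p_end = 1e-4,
    n_iterations = 50000L,
    k = 10L,
    grouped = TRUE,
    sens_floor = 0.99,
    spec_floor = 0.75,
    top_k = 5L,
    seed = 1L
  )
}

#' Load a run configuration with defaults filled in
#'
#' Reads a YAML (or JSON) configuration file and merges it over the
#' documented defaults: `w_neg` 0.0005, `p_start` 0.1, `p_end` 0.0001,
#' `treesize` 5, `minmass` 4, `method` classification, `n_iterations`
#' 50000, cross-validation `k` 10 (grouped), selection floors 0.99 / 0.75,
#' `top_k` 5, `seed` 1. Schema violations (unknown keys, wrong types) are
#' reported exhaustively in a single error.
#'
#' @param path Path to the configuration file, or `NULL` for pure defaults.
#' @return Named list of resolved settings.
#' @export
load_config <- function(path = NULL) {
  config <- config_defaults()
  if (is.null(path)) return(config)
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  problems <- character()
  unknown <- setdiff(names(user), names(config))
  if (length(unknown) > 0) {
    problems <- c(problems, paste0("unknown keys: ",
                                   paste(unknown, collapse = ", ")))
  }
  numeric_keys <- c("w_neg", "treesize", "minmass", "p_start", "p_end",
                    "n_iterations", "k", "sens_floor", "spec_floor",
                    "top_k", "seed")
  for (nm in intersect(names(user), names(config))) {
    v <- user[[nm]]
    if (nm %in% numeric_keys && !is.numeric(v)) {
      problems <- c(problems, paste0(nm, " must be numeric"))
    } else if (nm == "method" && !v %in% c("classification", "logistic")) {
      problems <- c(problems, "method must be classification or logistic")
    } else if (nm == "grouped" && !is.logical(v)) {
      problems <- c(problems, "grouped must be true or false")
    } else {
      config[[nm]] <- v
    }
  }
  if (length(problems) > 0) {
    abort(paste0("invalid config:\n", paste0("- ", problems, collapse = "\n")))
  }
  config
}

#' Turn a resolved run configuration into an annealing configuration
#'
#' @param config List from [load_config()].
#' @param seed Optional seed override (e.g. a CLI flag).
#' @return An [anneal_config()].
#' @export
as_anneal_config <- function(config, seed = NULL) {
  anneal_config(
    method = config$method, weights = score_weights(config$w_neg),
    treesize = config$treesize, minmass = config$minmass,
    p_start = config$p_start, p_end = config$p_end,
    n_iterations = config$n_iterations, seed = seed %||% config$seed
  )
}

# Provenance block written beside every artifact so outputs are
# reproducible bit for bit from the recorded configuration and seed.
write_provenance <- function(out_path, config, extra = list()) {
  prov <- c(list(
    package = "harmonizr",
    version = as.character(utils::packageVersion("harmonizr")),
    created = "run",
    config = config
  ), extra)
  jsonlite::write_json(prov, paste0(out_path, ".provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(NULL)
}
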