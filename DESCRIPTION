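Package: harmonizr
Title: Semi-Automated Variable Allocation for Harmonizing Epidemiological Datasets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for identifying which column of a heterogeneous cohort
    dataset corresponds to each target variable of a harmonized analysis
    dataset, as required in individual-participant-data meta-analysis.
    Columns are profiled into metadata features (name, label, type, scale
    level, distinct-value statistics, median, interquartile range); simple
    binary allocation rules over these features are combined into optimal
    Boolean trees by logic regression fitted with simulated annealing under
    a heavily class-weighted misclassification score; candidate source
    variables are then ranked per target and evaluated with sensitivity,
    specificity, PPV and NPV. Includes ROC-based cutoff calibration for
    threshold rules, a factorial tuning design with grouped cross-validation,
    and a synthetic-cohort generator with ground-truth mappings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
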