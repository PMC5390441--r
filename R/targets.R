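#' Distribution and naming templates for the packaged target variables
#'
#' One row per target variable of the packaged registry: the unit, the kind
#' of variable (continuous, binary, ordinal, nominal, date), plausible
#' distribution parameters, a plausible band for the sample median (used by
#' the authored threshold rules), name synonyms, and a verbose label. These
#' templates drive both the authored default rules and the synthetic-cohort
#' generator; distribution parameters are typical clinical ranges for the
#' unit in question (e.g. systolic blood pressure ~ Normal(130, 17) mmHg).
#'
#' @return A tibble with one row per target.
#' @export
target_templates <- function() {
  tmpl <- function(target, unit, vkind, vname, abbr, syns, label,
                   mu = NA, sigma = NA, lo = NA, hi = NA, p = NA,
                   n_levels = NA, dist = "norm") {
    tibble::tibble(
      target_name = target, unit = unit, vkind = vkind, vname = vname,
      abbr = abbr, syns = list(syns), label = label,
      mu = as.numeric(mu), sigma = as.numeric(sigma),
      lo = as.numeric(lo), hi = as.numeric(hi), p = as.numeric(p),
      n_levels = as.integer(n_levels), dist = dist
    )
  }
  dplyr::bind_rows(
    tmpl("Age", "years", "continuous", "age_years", "age", c("age"),
         "age of participant at baseline (years)", 55, 10, 30, 90),
    tmpl("BMI", "kg/m2", "continuous", "body_mass_index", "bmi",
         c("bmi", "body_mass"), "body mass index (kg/m2)", 27, 4, 18, 40),
    tmpl("Urea", "mg/dl", "continuous", "serum_urea", "urea", c("urea"),
         "serum urea (mg/dl)", 35, 10, 15, 70),
    tmpl("Cholesterol", "mg/dl", "continuous", "total_cholesterol", "tchol",
         c("chol", "tc"), "total cholesterol (mg/dl)", 210, 40, 160, 300),
    tmpl("Cholesterol SI", "mmol/l", "continuous", "total_cholesterol_mmol",
         "tchol_si", c("chol", "mmol"), "total cholesterol (mmol/l)",
         5.4, 1.0, 3.8, 7.8),
    tmpl("Creatinine", "mg/dl", "continuous", "serum_creatinine", "crea",
         c("crea"), "serum creatinine (mg/dl)", 0.95, 0.25, 0.4, 2.0),
    tmpl("Diabetes", "-", "binary", "diabetes_mellitus", "diab",
         c("diab"), "diabetes mellitus present (yes/no)", p = 0.10),
    tmpl("Education", "-", "ordinal", "education_level", "educ", c("educ"),
         "highest education level (4 categories)", n_levels = 4),
    tmpl("Ethnicity", "-", "nominal", "ethnicity", "ethn", c("ethn", "race"),
         "ethnic group (categorical)", n_levels = 5),
    tmpl("Event date", "-", "date", "event_date", "evdate",
         c("event", "date"), "date of first cardiovascular event"),
    tmpl("Fasting glucose", "mg/dl", "continuous", "fasting_glucose", "fglu",
         c("glu"), "fasting plasma glucose (mg/dl)", 95, 15, 70, 140),
    tmpl("Fasting glucose SI", "mmol/l", "continuous",
         "fasting_glucose_mmol", "fglu_si", c("glu", "mmol"),
         "fasting plasma glucose (mmol/l)", 5.3, 0.8, 3.9, 7.8),
    tmpl("Fibrinogen", "mg/dl", "continuous", "fibrinogen", "fib", c("fib"),
         "plasma fibrinogen (mg/dl)", 320, 70, 180, 480),
    tmpl("Hemoglobin", "g/dl", "continuous", "hemoglobin", "hb",
         c("hemogl", "hb"), "hemoglobin (g/dl)", 14, 1.5, 10, 18),
    tmpl("Hemoglobin SI", "g/l", "continuous", "hemoglobin_gl", "hb_si",
         c("hemogl", "hb"), "hemoglobin (g/l)", 140, 15, 100, 180),
    tmpl("Hba1c", "%", "continuous", "hba1c_percent", "hba1c",
         c("hba1c", "a1c"), "glycated hemoglobin hba1c (%)", 5.6, 0.8, 4, 9),
    tmpl("HDL cholesterol", "mg/dl", "continuous", "hdl_cholesterol", "hdl",
         c("hdl"), "hdl cholesterol (mg/dl)", 52, 14, 30, 85),
    tmpl("HDL cholesterol SI", "mmol/l", "continuous",
         "hdl_cholesterol_mmol", "hdl_si", c("hdl", "mmol"),
         "hdl cholesterol (mmol/l)", 1.35, 0.35, 0.7, 2.3),
    tmpl("History of CVD", "-", "binary", "history_cvd", "cvdhist",
         c("cvd", "hist"), "history of cardiovascular disease (yes/no)",
         p = 0.15),
    tmpl("Hs-CRP", "mg/l", "continuous", "hs_crp", "crp", c("crp"),
         "high-sensitivity c-reactive protein (mg/l)", log(2), 0.7,
         0.2, 10, dist = "lnorm"),
    tmpl("Hypertension", "-", "binary", "hypertension", "htn",
         c("hypert", "htn"), "hypertension present (yes/no)", p = 0.35),
    tmpl("Intima media thickness", "0.1 mm", "continuous", "imt_mean", "imt",
         c("imt", "intima"), "carotid intima media thickness (0.1 mm)",
         7.5, 1.3, 4.5, 11),
    tmpl("Intima media thickness SI", "mm", "continuous", "imt_mean_mm",
         "imt_si", c("imt", "intima"),
         "carotid intima media thickness (mm)", 0.75, 0.13, 0.45, 1.1),
    tmpl("Arterial diameter", "mm", "continuous", "carotid_diameter", "diam",
         c("diam"), "carotid artery lumen diameter (mm)", 7, 0.7, 5, 9),
    tmpl("Income", "-", "ordinal", "household_income", "income", c("income"),
         "household income category", n_levels = 5),
    tmpl("LDL cholesterol", "mg/dl", "continuous", "ldl_cholesterol", "ldl",
         c("ldl"), "ldl cholesterol (mg/dl)", 130, 35, 70, 200),
    tmpl("LDL cholesterol SI", "mmol/l", "continuous",
         "ldl_cholesterol_mmol", "ldl_si", c("ldl", "mmol"),
         "ldl cholesterol (mmol/l)", 3.2, 0.8, 1.8, 5.2),
    tmpl("Leukocytes", "1/ul", "continuous", "leukocyte_count", "wbc",
         c("leuk", "wbc"), "leukocyte count (1/ul)", 6500, 1700, 3500, 12000),
    tmpl("Dyslipidemia", "-", "binary", "dyslipidemia", "dyslip",
         c("dyslip"), "dyslipidemia present (yes/no)", p = 0.30),
    tmpl("Antidiabetic medication", "-", "binary", "antidiabetic_medication",
         "med_diab", c("diab", "med"),
         "use of antidiabetic medication (yes/no)", p = 0.08),
    tmpl("Antihypertensive medication", "-", "binary",
         "antihypertensive_medication", "med_htn", c("hypert", "med"),
         "use of antihypertensive medication (yes/no)", p = 0.30),
    tmpl("Lipid-lowering medication", "-", "binary",
         "lipid_lowering_medication", "med_lip", c("lipid", "med"),
         "use of lipid-lowering medication (yes/no)", p = 0.20),
    tmpl("Nicotine consumption", "Pack years", "continuous", "pack_years",
         "packyrs", c("pack", "nicotin"),
         "cumulative nicotine consumption (pack years)", 15, 8, 2, 50),
    tmpl("Carotid plaque", "-", "binary", "carotid_plaque", "plaque",
         c("plaque"), "carotid plaque present (yes/no)", p = 0.25),
    tmpl("Diastolic blood pressure", "mmHg", "continuous", "diastolic_bp",
         "dbp", c("diastol", "dbp"), "diastolic blood pressure (mmhg)",
         80, 10, 55, 100),
    tmpl("Systolic blood pressure", "mmHg", "continuous", "systolic_bp",
         "sbp", c("systol", "sbp"), "systolic blood pressure (mmhg)",
         130, 17, 100, 165),
    tmpl("Socioeconomic status", "-", "ordinal", "socioeconomic_status",
         "ses", c("socio", "ses"), "socioeconomic status (3 categories)",
         n_levels = 3),
    tmpl("Sex", "-", "binary", "sex", "sex", c("sex", "gender"),
         "sex of participant (0=female 1=male)", p = 0.5),
    tmpl("Smoking status", "-", "ordinal", "smoking_status", "smok",
         c("smok"), "smoking status (never/former/current)", n_levels = 3),
    tmpl("Triglycerides", "mg/dl", "continuous", "triglycerides", "trig",
         c("trig"), "triglycerides (mg/dl)", 140, 60, 80, 260),
    tmpl("Ultrasound date", "-", "date", "ultrasound_date", "usdate",
         c("ultraso", "date"), "date of ultrasound examination")
  )
}

template_dtype <- function(vkind) {
  switch(vkind, continuous = , binary = , ordinal = "number",
         nominal = "string", date = "date")
}

template_scale <- function(vkind) {
  switch(vkind, continuous = "ratio", binary = "dichotomous",
         ordinal = "ordinal", nominal = "nominal", date = "nominal")
}

#' The packaged default rule registry
#'
#' A curated rule set for the 41 packaged target variables. The per-target
#' rules are authored from the targets' units and typical clinical ranges:
#' substring rules on name synonyms and on the verbose label, a storage-type
#' rule, a scale-level rule, and (for continuous targets) a pair of median
#' threshold rules bracketing the plausible range. This registry is a
#' reconstruction shipped so the full pipeline is runnable out of the box;
#' production users supply their own registry via [read_registry()].
#'
#' @return A registry tibble: one row per rule, columns `target_name`,
#'   `unit`, `rule_id`, `kind`, `pattern`, `feature`, `direction`, `cutoff`.
#' @export
#' @examples
#' nrow(registry_targets(default_registry()))
default_registry <- function() {
  templates <- target_templates()
  rows <- purrr::pmap_dfr(
    list(seq_len(nrow(templates))),
    function(i) {
      t <- templates[i, ]
      syns <- t$syns[[1]]
      rules <- list()
      for (j in seq_along(syns)) {
        rules[[length(rules) + 1]] <-
          rule(paste0("name_", syns[j]), "name_contains", pattern = syns[j])
      }
      rules[[length(rules) + 1]] <-
        rule("label_match", "label_contains", pattern = t$label)
      rules[[length(rules) + 1]] <-
        rule("dtype", "dtype_is", pattern = template_dtype(t$vkind))
      rules[[length(rules) + 1]] <-
        rule("scale", "scale_is", pattern = template_scale(t$vkind))
      if (t$vkind == "continuous") {
        rules[[length(rules) + 1]] <- rule("median_lo", "threshold",
          feature = "median", direction = "gt", cutoff = t$lo)
        rules[[length(rules) + 1]] <- rule("median_hi", "threshold",
          feature = "median", direction = "lt", cutoff = t$hi)
      }
      dplyr::bind_rows(rules) |>
        dplyr::mutate(target_name = t$target_name, unit = t$unit,
                      .before = 1)
    }
  )
  new_registry(rows)
}
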