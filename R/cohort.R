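#' Therapy arm labels
#'
#' The eight therapy categories compared throughout the package, in display
#' order: the five most prevalent monotherapies, glibenclamide (kept because it
#' is the chemical substance of the Xiaoke Pill), the Xiaoke Pill combined with
#' any other agent, and a pooled "Others" category for all remaining plans.
#'
#' @return Character vector of the eight arm labels.
#' @export
arm_levels <- function() {
  c("Metformin", "Xiaoke Pill", "Other TCMs", "Gliclazide", "Acarbose",
    "Xiaoke Pill+", "Glibenclamide", "Others")
}

#' City labels of the five study sites
#' @return Character vector of city names (Beijing is the reference city).
#' @export
city_levels <- function() {
  c("Beijing", "Shenyang", "Chengdu", "Nanjing", "Guangzhou")
}

#' Medical insurance scheme labels
#' @return Character vector (URBMI is the reference scheme).
#' @export
insurance_levels <- function() {
  c("URBMI", "UEBMI", "NRCM", "government")
}

# the 15 monitored oral agents: 13 chemical drugs plus herbal TCMs and the
# Xiaoke Pill compound
monitored_agents <- function() {
  c("metformin", "phenformin",
    "glibenclamide", "glipizide", "gliquidone", "gliclazide", "glimepiride",
    "acarbose", "voglibose",
    "repaglinide", "nateglinide",
    "rosiglitazone", "pioglitazone",
    "tcms", "xiaoke pill")
}

#' Names of the 35 baseline covariate indicators
#'
#' Binary indicators built by [build_covariates()]: dummy groups for age,
#' education, city, income, insurance and diabetes duration (reference levels
#' encoded as all-zero), four behaviour flags, four comorbidity flags, and
#' clinically anchored cutoffs on the baseline measurements (BMI >= 24,
#' HbA1c < 6.5%, FBS < 7 mmol/L, SBP >= 140, DBP >= 90 mmHg, TC >= 5.2,
#' TG >= 1.7 mmol/L, EQ-5D >= 0.9, plus the baseline hypoglycemia report).
#'
#' @return Character vector of length 35.
#' @export
covariate_names <- function() {
  c("age_50_60", "age_60_70", "age_70plus",
    "male",
    "edu_lower_sec", "edu_upper_sec", "edu_tertiary",
    "city_shenyang", "city_chengdu", "city_nanjing", "city_guangzhou",
    "income_mid", "income_high",
    "ins_uebmi", "ins_nrcm", "ins_gov",
    "smoking", "drinking", "exercise", "diet_control",
    "duration_5_10", "duration_10plus",
    "heart_disease", "hypertension", "dyslipidemia", "stroke",
    "bmi_ge24", "hba1c_ctrl_bl", "fbs_lt7", "hypo_bl",
    "sbp_ge140", "dbp_ge90", "tc_ge52", "tg_ge17", "hrqol_ge09")
}

# columns a cohort table must carry
cohort_columns <- function() {
  c("patient_id", "city", "age_years", "sex", "education", "income_band",
    "insurance", "smoking", "drinking", "exercise", "diet_control",
    "duration_band", "heart_disease", "hypertension", "dyslipidemia", "stroke",
    "bmi", "fbs", "hba1c", "sbp", "dbp", "tc", "tg", "eq5d", "hypo_baseline",
    "drugs_baseline", paste0("drugs_fu", 1:4), paste0("hypo_fu", 1:4),
    "endpoint_hba1c", "endpoint_eq5d",
    "cost_inpatient", "cost_outpatient", "cost_otc")
}

#' Validate a cohort table
#'
#' Checks that a patient-level table carries all required columns, that the
#' baseline and endpoint measures are present and finite (complete-case policy:
#' missing values are an error, never imputed), that cost components are
#' nonnegative and that EQ-5D utilities lie in \[0, 1\].
#'
#' @param cohort A data frame with one row per patient.
#' @return The cohort, invisibly, as a tibble.
#' @export
validate_cohort <- function(cohort) {
  cohort <- tibble::as_tibble(cohort)
  missing_cols <- setdiff(cohort_columns(), names(cohort))
  if (length(missing_cols) > 0) {
    rlang::abort(
      paste0("cohort is missing columns: ", paste(missing_cols, collapse = ", ")),
      class = "oad_schema_error"
    )
  }
  numeric_cols <- c("age_years", "bmi", "fbs", "hba1c", "sbp", "dbp", "tc",
                    "tg", "eq5d", "endpoint_hba1c", "endpoint_eq5d",
                    "cost_inpatient", "cost_outpatient", "cost_otc")
  bad <- numeric_cols[vapply(numeric_cols,
                             function(v) any(!is.finite(cohort[[v]])),
                             logical(1))]
  if (length(bad) > 0) {
    rlang::abort(
      paste0("missing or non-finite values in: ", paste(bad, collapse = ", "),
             " (complete-case analysis; no imputation is performed)"),
      class = "oad_missing_data_error"
    )
  }
  cost_cols <- c("cost_inpatient", "cost_outpatient", "cost_otc")
  if (any(unlist(cohort[cost_cols]) < 0)) {
    rlang::abort("cost components must be nonnegative",
                 class = "oad_validation_error")
  }
  if (any(cohort$eq5d < 0 | cohort$eq5d > 1) ||
      any(cohort$endpoint_eq5d < 0 | cohort$endpoint_eq5d > 1)) {
    rlang::abort("EQ-5D utilities must lie in [0, 1]",
                 class = "oad_validation_error")
  }
  invisible(cohort)
}

#' Build the 35 baseline covariate indicators
#'
#' Codes every control variable as a 0/1 indicator using the clinical cutoffs:
#' age bands (reference < 50), sex, education bands (reference primary or
#' below), city dummies (reference Beijing), income bands (reference
#' < 1000 yuan/month), insurance dummies (reference URBMI), the four behaviour
#' flags, duration bands (reference < 5 years), the four comorbidities, and
#' BMI >= 24, baseline HbA1c < 6.5%, FBS < 7 mmol/L, baseline hypoglycemia,
#' SBP >= 140 mmHg, DBP >= 90 mmHg, TC >= 5.2 mmol/L, TG >= 1.7 mmol/L and
#' baseline EQ-5D >= 0.9. Reference categories are encoded as all-zero within
#' each dummy group.
#'
#' @param cohort A validated cohort table (see [validate_cohort()]).
#' @return A tibble with `patient_id` and the 35 indicator columns of
#'   [covariate_names()], all integer 0/1.
#' @export
build_covariates <- function(cohort) {
  cohort <- validate_cohort(cohort)
  city <- as.character(cohort$city)
  ins <- as.character(cohort$insurance)
  out <- tibble::tibble(
    patient_id   = as.character(cohort$patient_id),
    age_50_60    = as.integer(cohort$age_years >= 50 & cohort$age_years < 60),
    age_60_70    = as.integer(cohort$age_years >= 60 & cohort$age_years < 70),
    age_70plus   = as.integer(cohort$age_years >= 70),
    male         = as.integer(cohort$sex == 1),
    edu_lower_sec = as.integer(cohort$education == 2),
    edu_upper_sec = as.integer(cohort$education == 3),
    edu_tertiary  = as.integer(cohort$education == 4),
    city_shenyang  = as.integer(city == "Shenyang"),
    city_chengdu   = as.integer(city == "Chengdu"),
    city_nanjing   = as.integer(city == "Nanjing"),
    city_guangzhou = as.integer(city == "Guangzhou"),
    income_mid   = as.integer(cohort$income_band == 2),
    income_high  = as.integer(cohort$income_band == 3),
    ins_uebmi    = as.integer(ins == "UEBMI"),
    ins_nrcm     = as.integer(ins == "NRCM"),
    ins_gov      = as.integer(ins == "government"),
    smoking      = as.integer(cohort$smoking == 1),
    drinking     = as.integer(cohort$drinking == 1),
    exercise     = as.integer(cohort$exercise == 1),
    diet_control = as.integer(cohort$diet_control == 1),
    duration_5_10   = as.integer(cohort$duration_band == 2),
    duration_10plus = as.integer(cohort$duration_band == 3),
    heart_disease = as.integer(cohort$heart_disease == 1),
    hypertension  = as.integer(cohort$hypertension == 1),
    dyslipidemia  = as.integer(cohort$dyslipidemia == 1),
    stroke        = as.integer(cohort$stroke == 1),
    bmi_ge24      = as.integer(cohort$bmi >= 24),
    hba1c_ctrl_bl = as.integer(cohort$hba1c < 6.5),
    fbs_lt7       = as.integer(cohort$fbs < 7),
    hypo_bl       = as.integer(cohort$hypo_baseline == 1),
    sbp_ge140     = as.integer(cohort$sbp >= 140),
    dbp_ge90      = as.integer(cohort$dbp >= 90),
    tc_ge52       = as.integer(cohort$tc >= 5.2),
    tg_ge17       = as.integer(cohort$tg >= 1.7),
    hrqol_ge09    = as.integer(cohort$eq5d >= 0.9)
  )
  out
}

# normalize free-text drug names to the canonical dictionary form
normalize_drug <- function(x) {
  x <- tolower(trimws(gsub("[_]+", " ", x)))
  x <- gsub("\\s+", " ", x)
  x[x %in% c("tcm", "tcms", "other tcms")] <- "tcms"
  x[x %in% c("xiaoke", "xiaoke pill", "xiaokepill", "xiao ke wan")] <- "xiaoke pill"
  x
}

#' Split semicolon-delimited drug strings into sets
#'
#' @param x Character vector; each element lists drug names separated by `;`.
#' @return A list of character vectors (normalized, unique, sorted).
#' @export
parse_drug_list <- function(x) {
  lapply(strsplit(as.character(x), ";", fixed = TRUE), function(d) {
    d <- normalize_drug(d)
    sort(unique(d[nzchar(d)]))
  })
}

classify_one <- function(drugs) {
  drugs <- sort(unique(normalize_drug(drugs)))
  drugs <- drugs[nzchar(drugs)]
  if (length(drugs) == 0) {
    rlang::abort("cannot classify an empty drug set",
                 class = "oad_classification_error")
  }
  if (all(drugs == "insulin")) {
    rlang::abort("insulin-only users are excluded before classification",
                 class = "oad_classification_error")
  }
  unknown <- setdiff(drugs, c(monitored_agents(), "insulin"))
  if (length(unknown) > 0) {
    rlang::warn(paste0("unmonitored drug name(s) ",
                       paste(unknown, collapse = ", "),
                       "; plan classified under Others"),
                class = "oad_unknown_drug")
    if (!("xiaoke pill" %in% drugs)) return("Others")
  }
  if ("xiaoke pill" %in% drugs && length(drugs) >= 2) return("Xiaoke Pill+")
  if (length(drugs) == 1) {
    return(switch(drugs,
      "metformin"     = "Metformin",
      "xiaoke pill"   = "Xiaoke Pill",
      "tcms"          = "Other TCMs",
      "gliclazide"    = "Gliclazide",
      "acarbose"      = "Acarbose",
      "glibenclamide" = "Glibenclamide",
      "Others"))
  }
  "Others"
}

#' Classify a drug plan into a therapy arm
#'
#' Maps each set of concurrently used oral agents to one of the eight arms:
#' the singleton plans metformin, Xiaoke Pill, other TCMs, gliclazide,
#' acarbose and glibenclamide keep their own arm; any plan of two or more
#' agents containing the Xiaoke Pill is "Xiaoke Pill+"; every other plan
#' (including all remaining monotherapies and combinations) is "Others".
#' Drug names are matched case-insensitively against the dictionary of the 15
#' monitored oral agents; unmonitored names trigger a warning and fall into
#' "Others". Empty sets and insulin-only plans are errors (insulin users are
#' excluded upstream).
#'
#' @param drugs A list of character vectors (one set per patient), or a
#'   character vector of semicolon-delimited plans.
#' @return A factor with levels [arm_levels()].
#' @export
classify_therapy <- function(drugs) {
  if (is.character(drugs)) drugs <- parse_drug_list(drugs)
  if (!is.list(drugs)) drugs <- list(drugs)
  arms <- vapply(drugs, classify_one, character(1))
  factor(arms, levels = arm_levels())
}

#' Assign therapy arms under intent-to-treat and on-treatment rules
#'
#' The intent-to-treat (ITT) arm is the therapy observed at baseline. A
#' patient is *adherent* (eligible for the on-treatment cohort) when all four
#' follow-up drug sets equal the baseline set — no discontinuation, switching
#' or add-on at any wave.
#'
#' @param cohort A validated cohort table.
#' @return A tibble with `patient_id`, `arm` (factor, ITT assignment) and
#'   `adherent` (logical). The on-treatment cohort is the `adherent` subset,
#'   with identical arm labels.
#' @export
define_cohorts <- function(cohort) {
  cohort <- validate_cohort(cohort)
  base_sets <- parse_drug_list(cohort$drugs_baseline)
  arm <- classify_therapy(base_sets)
  fu_sets <- lapply(paste0("drugs_fu", 1:4),
                    function(v) parse_drug_list(cohort[[v]]))
  adherent <- rep(TRUE, nrow(cohort))
  for (w in 1:4) {
    adherent <- adherent & mapply(identical, base_sets, fu_sets[[w]])
  }
  tibble::tibble(
    patient_id = as.character(cohort$patient_id),
    arm = arm,
    adherent = as.logical(adherent)
  )
}

#' Derive the endpoint outcome vector
#'
#' Computes the four endpoint families: `hba1c_control` (1 iff endpoint HbA1c
#' is strictly below 6.5%), `hypo_incidence` (number of follow-up waves with a
#' reported hypoglycemic event, 0-4), `eq5d` (endpoint utility) and the three
#' cost components plus their exact sum `cost_total`, all in 1000-RMB units.
#'
#' @param cohort A validated cohort table.
#' @return A tibble with `patient_id` and the seven outcome columns.
#' @export
derive_outcomes <- function(cohort) {
  cohort <- validate_cohort(cohort)
  hypo <- as.matrix(cohort[paste0("hypo_fu", 1:4)])
  if (any(!hypo %in% c(0, 1))) {
    rlang::abort("follow-up hypoglycemia flags must be 0/1",
                 class = "oad_validation_error")
  }
  tibble::tibble(
    patient_id = as.character(cohort$patient_id),
    hba1c_control = as.integer(cohort$endpoint_hba1c < 6.5),
    hypo_incidence = as.integer(rowSums(hypo)),
    eq5d = cohort$endpoint_eq5d,
    cost_inpatient = cohort$cost_inpatient,
    cost_outpatient = cohort$cost_outpatient,
    cost_otc = cohort$cost_otc,
    cost_total = cohort$cost_inpatient + cohort$cost_outpatient + cohort$cost_otc
  )
}

#' Names of the seven endpoint outcomes
#' @return Character vector of outcome column names as produced by
#'   [derive_outcomes()].
#' @export
outcome_names <- function() {
  c("hba1c_control", "hypo_incidence", "eq5d",
    "cost_inpatient", "cost_outpatient", "cost_otc", "cost_total")
}
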