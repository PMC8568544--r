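#' Read a cohort from baseline and follow-up CSV files
#'
#' The baseline file holds one patient per row with demographic, behavioural,
#' comorbidity and measurement columns plus the baseline drug plan and the
#' endpoint outcomes. The follow-up file is long format with one row per
#' patient-wave: `patient_id`, `wave` (1-4), `drugs` (semicolon-delimited) and
#' `hypoglycemia` (0/1). The two are joined into the wide cohort layout used
#' throughout the package.
#'
#' @param baseline_path Path to the baseline+outcomes CSV.
#' @param followup_path Path to the long-format follow-up CSV.
#' @return A validated cohort tibble.
#' @export
read_cohort <- function(baseline_path, followup_path) {
  base <- readr::read_csv(baseline_path, show_col_types = FALSE)
  fu <- readr::read_csv(followup_path, show_col_types = FALSE)
  need <- c("patient_id", "wave", "drugs", "hypoglycemia")
  if (!all(need %in% names(fu))) {
    rlang::abort("follow-up file needs columns patient_id, wave, drugs, hypoglycemia",
                 class = "oad_schema_error")
  }
  if (!all(sort(unique(fu$wave)) == 1:4)) {
    rlang::abort("follow-up file must contain exactly waves 1-4",
                 class = "oad_schema_error")
  }
  fu$patient_id <- as.character(fu$patient_id)
  base$patient_id <- as.character(base$patient_id)
  wide <- tidyr::pivot_wider(
    fu,
    id_cols = "patient_id",
    names_from = "wave",
    values_from = c("drugs", "hypoglycemia"),
    names_glue = "{.value}_{wave}"
  )
  names(wide) <- sub("^drugs_(\\d)$", "drugs_fu\\1", names(wide))
  names(wide) <- sub("^hypoglycemia_(\\d)$", "hypo_fu\\1", names(wide))
  cohort <- dplyr::inner_join(base, wide, by = "patient_id")
  if (nrow(cohort) < nrow(base)) {
    rlang::abort("some patients lack complete follow-up records",
                 class = "oad_missing_data_error")
  }
  validate_cohort(cohort)
  tibble::as_tibble(cohort)
}

#' Write a cohort to baseline and follow-up CSV files
#'
#' Inverse of [read_cohort()]: splits the wide cohort table into a baseline
#' CSV and a long-format follow-up CSV.
#'
#' @param cohort A validated cohort tibble.
#' @param baseline_path,followup_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_cohort <- function(cohort, baseline_path, followup_path) {
  cohort <- validate_cohort(cohort)
  fu_cols <- c(paste0("drugs_fu", 1:4), paste0("hypo_fu", 1:4))
  base <- cohort[setdiff(names(cohort), fu_cols)]
  fu <- purrr::map_dfr(1:4, function(w) {
    tibble::tibble(
      patient_id = as.character(cohort$patient_id),
      wave = w,
      drugs = cohort[[paste0("drugs_fu", w)]],
      hypoglycemia = cohort[[paste0("hypo_fu", w)]]
    )
  })
  readr::write_csv(base, baseline_path)
  readr::write_csv(fu, followup_path)
  invisible(c(baseline_path, followup_path))
}
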