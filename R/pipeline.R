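#' Build a pipeline configuration
#'
#' @param mode `"synthetic"` (generate a cohort) or `"files"` (read CSVs).
#' @param baseline_path,followup_path Input CSVs for `mode = "files"`.
#' @param sim Simulation configuration for `mode = "synthetic"`; defaults to
#'   [sim_config()] with the given seed.
#' @param regime `"ITT"` (arms fixed at baseline) or `"on_treatment"`
#'   (restricted to patients who never changed plan).
#' @param estimators Which estimators to run; any of `"describe"`,
#'   `"adjust"`, `"ipw"`, `"dslasso"`.
#' @param alpha Significance level for letter displays.
#' @param seed Integer seed (used in synthetic mode).
#' @param out_dir Output directory for the report bundle.
#' @return A list of class `oad_pipeline_config`.
#' @export
pipeline_config <- function(mode = c("synthetic", "files"),
                            baseline_path = NULL, followup_path = NULL,
                            sim = NULL,
                            regime = c("ITT", "on_treatment"),
                            estimators = c("describe", "adjust", "ipw",
                                           "dslasso"),
                            alpha = 0.05, seed = 1L, out_dir = tempfile("oad_")) {
  mode <- match.arg(mode)
  regime <- match.arg(regime)
  stopifnot(alpha > 0, alpha < 1)
  estimators <- match.arg(estimators, several.ok = TRUE)
  if (mode == "files" && (is.null(baseline_path) || is.null(followup_path))) {
    rlang::abort("files mode needs baseline_path and followup_path",
                 class = "oad_config_error")
  }
  if (is.null(sim)) sim <- sim_config(seed = seed)
  structure(list(mode = mode, baseline_path = baseline_path,
                 followup_path = followup_path, sim = sim, regime = regime,
                 estimators = estimators, alpha = alpha, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "oad_pipeline_config")
}

#' Run the full comparison pipeline
#'
#' Orchestrates generate/load, therapy classification, covariate and outcome
#' derivation, and the requested estimators, writing plain-CSV analogues of
#' the study tables to `config$out_dir`:
#'
#' * `arm_counts.csv` — arm sizes, proportions, cumulative proportions
#' * `baseline_balance.csv` — covariate means per arm with ANOVA p-values
#' * `unadjusted_outcomes.csv` — subgroup means, SEs and letter groups
#' * `adjusted_coefficients.csv` — OLS coefficients with stars (per outcome)
#' * `adjusted_margins.csv` — predictive margins with letter groups
#' * `ipw_outcomes.csv` — inverse-probability-weighted means and SEs
#' * `weighted_balance.csv` — propensity-weighted balance with p-values
#' * `selected_covariates.csv` — double-selection marks per outcome
#' * `double_selection_margins.csv` — post-selection margins with letters
#' * `manifest.json` — seed, regime, sizes, package version, config hash
#'
#' Outputs are deterministic: the same configuration and seed produce
#' byte-identical bundles.
#'
#' @param config An [pipeline_config()] object.
#' @return Invisibly, a list with the cohort, assignments and every table.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "oad_pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      rlang::abort(paste0("[", name, "] ", conditionMessage(e)), parent = e)
    })
  }

  cohort <- stage("input", {
    if (config$mode == "synthetic") generate_cohort(config$sim)
    else read_cohort(config$baseline_path, config$followup_path)
  })

  assign_tbl <- stage("classify", define_cohorts(cohort))
  keep <- if (config$regime == "on_treatment") assign_tbl$adherent else
    rep(TRUE, nrow(cohort))
  cohort_use <- cohort[keep, , drop = FALSE]
  arm <- droplevels(assign_tbl$arm[keep])
  covariates <- stage("covariates", build_covariates(cohort_use))
  outcomes <- stage("outcomes", derive_outcomes(cohort_use))
  xmat <- covariate_matrix(covariates)
  binary_type <- function(o) if (o == "hba1c_control") "binary" else "continuous"

  tables <- list()

  counts <- as.data.frame(table(arm), stringsAsFactors = FALSE)
  names(counts) <- c("arm", "n")
  counts$proportion <- round(100 * counts$n / sum(counts$n), 2)
  counts$cumulative <- round(cumsum(100 * counts$n / sum(counts$n)), 2)
  tables$arm_counts <- tibble::as_tibble(counts)

  tables$baseline_balance <- stage("describe", balance_table(covariates, arm))

  if ("describe" %in% config$estimators) {
    tables$unadjusted_outcomes <- stage("describe", purrr::map_dfr(
      outcome_names(), function(o) {
        dplyr::mutate(
          subgroup_summary(outcomes[[o]], arm, type = binary_type(o),
                           alpha = config$alpha),
          outcome = o, .before = 1)
      }))
  }

  if ("adjust" %in% config$estimators) {
    fits <- stage("adjust", lapply(stats::setNames(nm = outcome_names()),
                                   function(o) {
      fit_outcome_model(outcomes[[o]], arm, xmat)
    }))
    tables$adjusted_coefficients <- purrr::map_dfr(
      outcome_names(), function(o) {
        dplyr::mutate(fits[[o]]$coefficients, outcome = o, .before = 1)
      })
    tables$adjusted_margins <- purrr::map_dfr(outcome_names(), function(o) {
      dplyr::mutate(predictive_margins(fits[[o]], alpha = config$alpha),
                    outcome = o, .before = 1)
    })
  }

  if ("ipw" %in% config$estimators) {
    prop <- stage("ipw", fit_propensity(arm, xmat))
    wts <- stage("ipw", compute_weights(prop))
    tables$ipw_outcomes <- purrr::map_dfr(outcome_names(), function(o) {
      dplyr::mutate(
        weighted_outcomes(outcomes[[o]], prop$arm, wts$raw,
                          alpha = config$alpha),
        outcome = o, .before = 1)
    })
    tables$weighted_balance <- stage(
      "ipw", weighted_balance(covariates, prop$arm, wts$raw))
  }

  if ("dslasso" %in% config$estimators) {
    pool <- stage("dslasso", build_candidate_pool(covariates))
    ds <- stage("dslasso", lapply(stats::setNames(nm = outcome_names()),
                                  function(o) {
      sel <- double_select(outcomes[[o]], arm, pool)
      post <- post_selection_fit(outcomes[[o]], arm, pool, sel$union,
                                 alpha = config$alpha)
      list(sel = sel, post = post)
    }))
    marks <- sapply(outcome_names(), function(o) {
      ifelse(colnames(pool) %in% ds[[o]]$sel$union, "Y", "")
    })
    tables$selected_covariates <- dplyr::mutate(
      tibble::as_tibble(marks), covariate = colnames(pool), .before = 1)
    tables$double_selection_margins <- purrr::map_dfr(
      outcome_names(), function(o) {
        dplyr::mutate(ds[[o]]$post$margins, outcome = o, .before = 1)
      })
  }

  for (nm in names(tables)) {
    readr::write_csv(tables[[nm]], file.path(config$out_dir,
                                             paste0(nm, ".csv")))
  }
  manifest <- list(
    seed = config$seed,
    mode = config$mode,
    regime = config$regime,
    alpha = config$alpha,
    n_input = nrow(cohort),
    n_analyzed = nrow(cohort_use),
    estimators = config$estimators,
    package_version = as.character(utils::packageVersion("oadcompare")),
    # hash over the scientific configuration only (paths are incidental)
    config_hash = rlang::hash(config[setdiff(names(unclass(config)),
                                             "out_dir")])
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(c(list(cohort = cohort, assignments = assign_tbl,
                   manifest = manifest), tables))
}
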