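#' Default covariate marginal prevalences
#'
#' Whole-sample prevalence of each of the 35 baseline indicators in the
#' multicenter cohort the generator emulates (1903 type-2 diabetes patients
#' across five Chinese cities). Values are proportions in \[0, 1\].
#'
#' @return Named numeric vector over [covariate_names()].
#' @export
default_covariate_marginals <- function() {
  c(age_50_60 = 0.25, age_60_70 = 0.33, age_70plus = 0.27,
    male = 0.44,
    edu_lower_sec = 0.36, edu_upper_sec = 0.24, edu_tertiary = 0.13,
    city_shenyang = 0.23, city_chengdu = 0.21, city_nanjing = 0.19,
    city_guangzhou = 0.20,
    income_mid = 0.38, income_high = 0.36,
    ins_uebmi = 0.64, ins_nrcm = 0.10, ins_gov = 0.05,
    smoking = 0.20, drinking = 0.25, exercise = 0.79, diet_control = 0.90,
    duration_5_10 = 0.26, duration_10plus = 0.24,
    heart_disease = 0.21, hypertension = 0.49, dyslipidemia = 0.20,
    stroke = 0.08,
    bmi_ge24 = 0.58, hba1c_ctrl_bl = 0.39, fbs_lt7 = 0.45, hypo_bl = 0.11,
    sbp_ge140 = 0.40, dbp_ge90 = 0.26, tc_ge52 = 0.39, tg_ge17 = 0.41,
    hrqol_ge09 = 0.48)
}

# mutually exclusive dummy groups among the 35 indicators
dummy_groups <- function() {
  list(age = c("age_50_60", "age_60_70", "age_70plus"),
       education = c("edu_lower_sec", "edu_upper_sec", "edu_tertiary"),
       city = c("city_shenyang", "city_chengdu", "city_nanjing",
                "city_guangzhou"),
       income = c("income_mid", "income_high"),
       insurance = c("ins_uebmi", "ins_nrcm", "ins_gov"),
       duration = c("duration_5_10", "duration_10plus"))
}

#' Default baseline arm shares
#' @return Named numeric vector of the eight arm shares (sums to 1).
#' @export
default_arm_shares <- function() {
  stats::setNames(
    c(203, 233, 137, 128, 110, 177, 12, 903) / 1903,
    arm_levels()
  )
}

#' Default true per-arm outcome margins
#'
#' Population-average potential-outcome means for each arm and outcome: the
#' proportion reaching endpoint HbA1c < 6.5%, the one-year hypoglycemia
#' incidence (0-4 count mean), the endpoint EQ-5D utility, and the three cost
#' components in 1000-RMB units. `cost_total` is implied by the component sum.
#'
#' @return An 8 x 6 numeric matrix (arms by outcomes).
#' @export
default_true_margins <- function() {
  m <- rbind(
    "Metformin"     = c(0.33, 0.35, 0.89, 4.28, 3.42, 0.84),
    "Xiaoke Pill"   = c(0.45, 0.42, 0.90, 1.63, 2.90, 0.81),
    "Other TCMs"    = c(0.36, 0.48, 0.89, 3.02, 3.87, 1.54),
    "Gliclazide"    = c(0.41, 0.43, 0.88, 1.94, 3.83, 0.74),
    "Acarbose"      = c(0.40, 0.40, 0.88, 4.44, 4.70, 1.18),
    "Xiaoke Pill+"  = c(0.43, 0.36, 0.87, 1.99, 3.40, 0.89),
    "Glibenclamide" = c(0.28, 0.42, 0.89, 0.53, 3.26, 0.34),
    "Others"        = c(0.36, 0.44, 0.89, 3.13, 5.07, 0.87)
  )
  colnames(m) <- c("hba1c_control", "hypo_incidence", "eq5d",
                   "cost_inpatient", "cost_outpatient", "cost_otc")
  m
}

#' Default multinomial assignment coefficients
#'
#' Log-odds coefficients (reference arm Metformin) of the covariates that
#' drive therapy choice, emulating the imbalance observed across real arms:
#' herbal TCM users concentrated in Shenyang with longer disease duration and
#' more heart disease, gliclazide users concentrated in Nanjing, Xiaoke Pill
#' users with better baseline glycemic markers and less hypertension, and
#' combination users concentrated in Guangzhou with higher income. Setting all
#' entries to zero gives unconfounded assignment.
#'
#' @return Named list (one element per non-reference arm) of named numeric
#'   coefficient vectors over covariates.
#' @export
default_assignment_coefficients <- function() {
  list(
    "Xiaoke Pill" = c(hba1c_ctrl_bl = 0.5, fbs_lt7 = 0.5,
                      hypertension = -0.6, city_shenyang = 0.4),
    "Other TCMs" = c(city_shenyang = 2.2, heart_disease = 0.9,
                     duration_10plus = 0.8, hba1c_ctrl_bl = -0.5),
    "Gliclazide" = c(city_nanjing = 1.6, duration_5_10 = 0.7),
    "Acarbose" = c(income_high = 0.8, hba1c_ctrl_bl = 0.4),
    "Xiaoke Pill+" = c(city_guangzhou = 1.3, income_high = 0.6,
                       hba1c_ctrl_bl = 0.3, hypertension = -0.3),
    "Glibenclamide" = c(city_nanjing = 0.8),
    "Others" = c(city_nanjing = 0.5, income_high = 0.3, hba1c_ctrl_bl = -0.3)
  )
}

#' Default covariate effects on the outcomes
#'
#' Additive effects on each outcome's mean (probability scale for the binary
#' endpoint, per-wave probability scale for hypoglycemia, outcome units
#' otherwise), applied to mean-centered indicators so the configured arm
#' margins stay the population-average truth. Magnitudes are scaled so that
#' implied probabilities stay strictly inside (0, 1) for every covariate
#' pattern under the default margins.
#'
#' @return Named list over outcomes of named numeric vectors.
#' @export
default_outcome_effects <- function() {
  list(
    hba1c_control = c(hba1c_ctrl_bl = 0.13, fbs_lt7 = 0.06,
                      city_chengdu = 0.12, city_nanjing = 0.06,
                      city_guangzhou = 0.10, age_60_70 = -0.06,
                      age_70plus = -0.05, duration_10plus = -0.04,
                      hypertension = 0.03),
    hypo_incidence = c(hypo_bl = 0.04, hrqol_ge09 = -0.02,
                       city_shenyang = 0.03),
    eq5d = c(hrqol_ge09 = 0.03, stroke = -0.03, age_70plus = -0.02,
             exercise = 0.02),
    cost_inpatient = c(age_60_70 = 0.8, age_70plus = 1.0, exercise = -0.6,
                       stroke = 0.5, duration_10plus = 0.5,
                       hrqol_ge09 = -0.5),
    cost_outpatient = c(city_shenyang = -2.0, city_chengdu = -1.2,
                        city_nanjing = -1.8, city_guangzhou = -1.5,
                        age_50_60 = 0.5, age_60_70 = 0.4, age_70plus = 0.5,
                        heart_disease = 0.4),
    cost_otc = c(city_shenyang = 0.8, city_chengdu = 0.4,
                 heart_disease = 0.2, duration_10plus = 0.2)
  )
}

#' Build a simulation configuration
#'
#' Bundles every knob of the synthetic cohort generator. Defaults reproduce
#' the structure of the real multicenter cohort: 1903 patients, covariate
#' marginals from the observed whole-sample prevalences, arm shares from the
#' observed baseline therapy distribution (down to the 12-patient
#' glibenclamide arm), confounded multinomial assignment, and true arm margins
#' equal to the covariate-adjusted estimates of the real study.
#'
#' @param n_patients Cohort size.
#' @param covariate_marginals Named prevalence vector over [covariate_names()].
#' @param arm_shares Named target arm shares (used to calibrate assignment
#'   intercepts at the average covariate vector).
#' @param assignment_coefficients Named list of per-arm log-odds coefficient
#'   vectors (reference Metformin); `NULL` entries mean zero. Use
#'   `confounding = FALSE` to zero them all.
#' @param true_margins 8 x 6 matrix of per-arm potential-outcome means.
#' @param outcome_effects Named list of covariate effects per outcome.
#' @param noise_sd Named SDs for the continuous outcomes (eq5d and the three
#'   cost components).
#' @param adherence_prob Probability that a patient keeps the baseline plan
#'   through all four follow-ups (on-treatment eligibility).
#' @param confounding If `FALSE`, all assignment coefficients are set to zero.
#' @param binary_mechanism `"linear"` (linear-probability; the configured
#'   margins are exactly the potential-outcome means) or `"logistic"` (for
#'   misspecification experiments; margins then hold on the logit scale).
#' @param seed Integer seed; a fixed seed makes [generate_cohort()] output
#'   byte-identical.
#' @return A list of class `oad_sim_config`.
#' @export
sim_config <- function(n_patients = 1903,
                       covariate_marginals = default_covariate_marginals(),
                       arm_shares = default_arm_shares(),
                       assignment_coefficients = default_assignment_coefficients(),
                       true_margins = default_true_margins(),
                       outcome_effects = default_outcome_effects(),
                       noise_sd = c(eq5d = 0.05, cost_inpatient = 0.9,
                                    cost_outpatient = 0.8, cost_otc = 0.25),
                       adherence_prob = 878 / 1903,
                       confounding = TRUE,
                       binary_mechanism = c("linear", "logistic"),
                       seed = 1L) {
  binary_mechanism <- match.arg(binary_mechanism)
  stopifnot(n_patients >= 1)
  if (!setequal(names(covariate_marginals), covariate_names())) {
    rlang::abort("covariate_marginals must be named over covariate_names()",
                 class = "oad_config_error")
  }
  covariate_marginals <- covariate_marginals[covariate_names()]
  if (any(covariate_marginals < 0 | covariate_marginals > 1)) {
    rlang::abort("covariate marginals must lie in [0, 1]",
                 class = "oad_config_error")
  }
  for (g in dummy_groups()) {
    if (sum(covariate_marginals[g]) > 1 + 1e-12) {
      rlang::abort("dummy-group marginals must sum to at most 1",
                   class = "oad_config_error")
    }
  }
  if (!setequal(names(arm_shares), arm_levels()) ||
      abs(sum(arm_shares) - 1) > 1e-8) {
    rlang::abort("arm_shares must be named over arm_levels() and sum to 1",
                 class = "oad_config_error")
  }
  arm_shares <- arm_shares[arm_levels()]
  if (!confounding) {
    assignment_coefficients <- lapply(assignment_coefficients, function(b) b * 0)
  }
  if (!identical(rownames(true_margins), arm_levels())) {
    rlang::abort("true_margins rows must be arm_levels() in order",
                 class = "oad_config_error")
  }
  structure(
    list(n_patients = as.integer(n_patients),
         covariate_marginals = covariate_marginals,
         arm_shares = arm_shares,
         assignment_coefficients = assignment_coefficients,
         true_margins = true_margins,
         outcome_effects = outcome_effects,
         noise_sd = noise_sd,
         adherence_prob = adherence_prob,
         binary_mechanism = binary_mechanism,
         seed = as.integer(seed)),
    class = "oad_sim_config"
  )
}

# draw the 35-indicator matrix with mutually exclusive dummy groups
draw_covariates <- function(n, marginals) {
  x <- matrix(0L, n, length(covariate_names()),
              dimnames = list(NULL, covariate_names()))
  grouped <- unlist(dummy_groups(), use.names = FALSE)
  for (g in dummy_groups()) {
    p <- c(1 - sum(marginals[g]), marginals[g])
    draw <- sample.int(length(p), n, replace = TRUE, prob = p)
    for (j in seq_along(g)) x[, g[j]] <- as.integer(draw == j + 1L)
  }
  for (v in setdiff(covariate_names(), grouped)) {
    x[, v] <- stats::rbinom(n, 1, marginals[v])
  }
  x
}

# centered covariate contribution to an outcome mean
effect_shift <- function(x, beta, marginals) {
  if (is.null(beta) || length(beta) == 0) return(rep(0, nrow(x)))
  bad <- setdiff(names(beta), colnames(x))
  if (length(bad) > 0) {
    rlang::abort(paste0("unknown covariates in outcome effects: ",
                        paste(bad, collapse = ", ")),
                 class = "oad_config_error")
  }
  drop(x[, names(beta), drop = FALSE] %*% beta) - sum(beta * marginals[names(beta)])
}

# multinomial assignment probabilities at each covariate row
assignment_probabilities <- function(x, config) {
  arms <- arm_levels()
  mu <- config$covariate_marginals
  eta <- matrix(0, nrow(x), length(arms), dimnames = list(NULL, arms))
  for (a in arms[-1]) {
    beta <- config$assignment_coefficients[[a]]
    lin <- if (is.null(beta) || length(beta) == 0) 0 else
      drop(x[, names(beta), drop = FALSE] %*% beta) - sum(beta * mu[names(beta)])
    # intercept calibrated so the linear predictor at the average covariate
    # vector reproduces the target log-odds against the reference arm
    eta[, a] <- log(config$arm_shares[[a]] / config$arm_shares[[1]]) + lin
  }
  p <- exp(eta - apply(eta, 1, max))
  p / rowSums(p)
}

# continuous value consistent with a binary indicator, uniform within range
fill_measure <- function(ind, yes_range, no_range) {
  n <- length(ind)
  ifelse(ind == 1,
         stats::runif(n, yes_range[1], yes_range[2]),
         stats::runif(n, no_range[1], no_range[2]))
}

arm_drug_plans <- function() {
  c("Metformin" = "metformin",
    "Xiaoke Pill" = "Xiaoke Pill",
    "Other TCMs" = "TCMs",
    "Gliclazide" = "gliclazide",
    "Acarbose" = "acarbose",
    "Xiaoke Pill+" = "Xiaoke Pill;metformin",
    "Glibenclamide" = "glibenclamide",
    "Others" = "gliclazide;metformin")
}

#' Generate a synthetic cohort with known ground truth
#'
#' Draws covariates as mutually exclusive dummies within groups, assigns each
#' patient to one of the eight therapy arms from a multinomial logit on the
#' covariates (confounded whenever assignment coefficients are nonzero), and
#' generates outcomes around the configured per-arm margins: a
#' linear-probability Bernoulli mechanism for glycemic control (with a
#' consistent continuous endpoint HbA1c), per-wave Bernoulli hypoglycemia
#' flags (so the incidence is binomial with 4 trials), Gaussian EQ-5D censored
#' into \[0, 1\], and Gaussian cost components floored at zero. Baseline drug
#' plans match the assigned arm and follow-up plans deviate (add-on from a
#' random wave onward) for the non-adherent fraction.
#'
#' The true assignment, per-patient assignment probabilities and the
#' configuration are attached as attributes (see [cohort_truth()]).
#'
#' @param config An [sim_config()] object.
#' @return A validated cohort tibble of `config$n_patients` rows.
#' @export
generate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "oad_sim_config"))
  set.seed(config$seed)
  n <- config$n_patients
  mu <- config$covariate_marginals
  x <- draw_covariates(n, mu)

  probs <- assignment_probabilities(x, config)
  arm_idx <- apply(probs, 1, function(p) sample.int(length(p), 1, prob = p))
  arm <- factor(arm_levels()[arm_idx], levels = arm_levels())

  margins <- config$true_margins
  eff <- config$outcome_effects

  p_ctrl <- margins[arm_idx, "hba1c_control"] +
    effect_shift(x, eff$hba1c_control, mu)
  if (config$binary_mechanism == "logistic") {
    p_ctrl <- stats::plogis(stats::qlogis(
      pmin(pmax(margins[arm_idx, "hba1c_control"], 1e-6), 1 - 1e-6)) +
      effect_shift(x, eff$hba1c_control, mu))
  }
  if (any(p_ctrl < -0.05 | p_ctrl > 1.05)) {
    rlang::abort("implied control probability outside [0, 1] beyond tolerance; rescale outcome effects",
                 class = "oad_config_error")
  }
  p_ctrl <- pmin(pmax(p_ctrl, 0.01), 0.99)
  ctrl <- stats::rbinom(n, 1, p_ctrl)
  endpoint_hba1c <- ifelse(ctrl == 1,
                           stats::runif(n, 5.6, 6.49),
                           stats::runif(n, 6.5, 9.5))

  p_hypo <- margins[arm_idx, "hypo_incidence"] / 4 +
    effect_shift(x, eff$hypo_incidence, mu)
  if (any(p_hypo < -0.05 | p_hypo > 1.05)) {
    rlang::abort("implied hypoglycemia probability outside [0, 1] beyond tolerance",
                 class = "oad_config_error")
  }
  p_hypo <- pmin(pmax(p_hypo, 0.001), 0.999)
  hypo_fu <- matrix(stats::rbinom(4L * n, 1, rep(p_hypo, 4)), n, 4)

  eq5d_end <- margins[arm_idx, "eq5d"] + effect_shift(x, eff$eq5d, mu) +
    stats::rnorm(n, 0, config$noise_sd[["eq5d"]])
  eq5d_end <- pmin(pmax(eq5d_end, 0), 1)

  cost <- sapply(c("cost_inpatient", "cost_outpatient", "cost_otc"),
                 function(k) {
                   pmax(0, margins[arm_idx, k] + effect_shift(x, eff[[k]], mu) +
                          stats::rnorm(n, 0, config$noise_sd[[k]]))
                 })

  plans <- arm_drug_plans()[as.character(arm)]
  adherent <- stats::rbinom(n, 1, config$adherence_prob) == 1
  change_wave <- sample.int(4, n, replace = TRUE)
  addon <- ifelse(grepl("acarbose", plans), "voglibose", "acarbose")
  drugs_fu <- matrix(rep(plans, 4), n, 4)
  for (w in 1:4) {
    alter <- !adherent & change_wave <= w
    drugs_fu[alter, w] <- paste(plans[alter], addon[alter], sep = ";")
  }

  city_draw <- x[, dummy_groups()$city, drop = FALSE]
  city <- city_levels()[1 + drop(city_draw %*% seq_len(4))]
  ins_draw <- x[, dummy_groups()$insurance, drop = FALSE]
  insurance <- insurance_levels()[1 + drop(ins_draw %*% seq_len(3))]
  age_band <- 1 + drop(x[, dummy_groups()$age] %*% seq_len(3))
  age_lo <- c(30, 50, 60, 70)[age_band]
  age_hi <- c(49.9, 59.9, 69.9, 85)[age_band]

  cohort <- tibble::tibble(
    patient_id = sprintf("P%05d", seq_len(n)),
    city = city,
    age_years = stats::runif(n, age_lo, age_hi),
    sex = x[, "male"],
    education = 1 + drop(x[, dummy_groups()$education] %*% seq_len(3)),
    income_band = 1 + drop(x[, dummy_groups()$income] %*% seq_len(2)),
    insurance = insurance,
    smoking = x[, "smoking"],
    drinking = x[, "drinking"],
    exercise = x[, "exercise"],
    diet_control = x[, "diet_control"],
    duration_band = 1 + drop(x[, dummy_groups()$duration] %*% seq_len(2)),
    heart_disease = x[, "heart_disease"],
    hypertension = x[, "hypertension"],
    dyslipidemia = x[, "dyslipidemia"],
    stroke = x[, "stroke"],
    bmi = fill_measure(x[, "bmi_ge24"], c(24, 32), c(18, 23.9)),
    fbs = fill_measure(x[, "fbs_lt7"], c(4.5, 6.9), c(7, 12)),
    hba1c = fill_measure(x[, "hba1c_ctrl_bl"], c(5.5, 6.49), c(6.5, 10)),
    sbp = fill_measure(x[, "sbp_ge140"], c(140, 180), c(100, 139)),
    dbp = fill_measure(x[, "dbp_ge90"], c(90, 110), c(60, 89)),
    tc = fill_measure(x[, "tc_ge52"], c(5.2, 8), c(3, 5.1)),
    tg = fill_measure(x[, "tg_ge17"], c(1.7, 4), c(0.5, 1.69)),
    eq5d = fill_measure(x[, "hrqol_ge09"], c(0.9, 1), c(0.5, 0.89)),
    hypo_baseline = x[, "hypo_bl"],
    drugs_baseline = unname(plans),
    drugs_fu1 = drugs_fu[, 1], drugs_fu2 = drugs_fu[, 2],
    drugs_fu3 = drugs_fu[, 3], drugs_fu4 = drugs_fu[, 4],
    hypo_fu1 = hypo_fu[, 1], hypo_fu2 = hypo_fu[, 2],
    hypo_fu3 = hypo_fu[, 3], hypo_fu4 = hypo_fu[, 4],
    endpoint_hba1c = endpoint_hba1c,
    endpoint_eq5d = eq5d_end,
    cost_inpatient = cost[, "cost_inpatient"],
    cost_outpatient = cost[, "cost_outpatient"],
    cost_otc = cost[, "cost_otc"]
  )
  attr(cohort, "true_arm") <- arm
  attr(cohort, "true_propensity") <- probs
  attr(cohort, "sim_config") <- config
  cohort
}

#' Ground truth attached to a synthetic cohort
#'
#' @param cohort A cohort produced by [generate_cohort()].
#' @return List with `arm` (true assignment factor), `propensity`
#'   (n x 8 matrix of true assignment probabilities), `margins` (configured
#'   true per-arm outcome means) and `config`.
#' @export
cohort_truth <- function(cohort) {
  config <- attr(cohort, "sim_config")
  if (is.null(config)) {
    rlang::abort("cohort carries no simulation ground truth",
                 class = "oad_validation_error")
  }
  list(arm = attr(cohort, "true_arm"),
       propensity = attr(cohort, "true_propensity"),
       margins = config$true_margins,
       config = config)
}

#' Deterministic fixture cohort with the published arm and city counts
#'
#' A 1903-patient cohort whose baseline therapy arms have exactly the sizes
#' 203 (metformin), 233 (Xiaoke Pill), 137 (other TCMs), 128 (gliclazide),
#' 110 (acarbose), 177 (Xiaoke Pill+), 12 (glibenclamide) and 903 (others),
#' and whose city subsamples are exactly 314 (Beijing), 440 (Shenyang),
#' 403 (Chengdu), 366 (Nanjing) and 380 (Guangzhou). All patients adhere to
#' their baseline plan through every follow-up. Useful for exercising the
#' classification, counting and reporting paths against known totals.
#'
#' @return A validated cohort tibble of 1903 rows.
#' @export
fixture_cohort <- function() {
  config <- sim_config(n_patients = 1903, confounding = FALSE, seed = 402153L)
  cohort <- generate_cohort(config)
  arm_counts <- c(203, 233, 137, 128, 110, 177, 12, 903)
  arm <- rep(arm_levels(), arm_counts)
  plans <- unname(arm_drug_plans()[arm])
  cohort$drugs_baseline <- plans
  for (w in 1:4) cohort[[paste0("drugs_fu", w)]] <- plans
  city_counts <- c(Beijing = 314, Shenyang = 440, Chengdu = 403,
                   Nanjing = 366, Guangzhou = 380)
  cohort$city <- rep(names(city_counts), city_counts)
  attr(cohort, "true_arm") <- factor(arm, levels = arm_levels())
  cohort
}
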