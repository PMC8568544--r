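#' Fit the multinomial propensity model
#'
#' Maximum-likelihood multinomial logistic regression of arm membership on
#' baseline covariate indicators. Arms smaller than `min_arm_n` are merged
#' into `merge_into` before fitting, since inverse probability weighting needs
#' enough observations in every arm (with the default cohort this merges the
#' ~12-patient glibenclamide arm into "Others"). Coefficient divergence —
#' the signature of separation, where some fitted probabilities collapse to
#' 0/1 — is detected and reported with the offending covariates.
#'
#' @param arm Factor of arm assignments.
#' @param covariates Tibble/matrix of covariate indicators.
#' @param min_arm_n Minimum arm size before merging (default 30).
#' @param merge_into Arm label that absorbs small arms (default `"Others"`).
#' @param reltol Relative convergence tolerance of the likelihood
#'   optimization.
#' @return An object of class `oad_propensity`: list with `probabilities`
#'   (n x K matrix, rows summing to 1), `coefficients` (per non-reference arm),
#'   `arm` (the possibly merged factor), `arm_levels`, `merged`, `model`.
#' @export
fit_propensity <- function(arm, covariates, min_arm_n = 30,
                           merge_into = "Others", reltol = 1e-12) {
  arm <- droplevels(as.factor(arm))
  x <- covariate_matrix(covariates)
  stopifnot(nrow(x) == length(arm))
  tab <- table(arm)
  small <- names(tab)[tab < min_arm_n & names(tab) != merge_into]
  if (length(small) > 0) {
    lv <- as.character(arm)
    lv[lv %in% small] <- merge_into
    arm <- factor(lv, levels = setdiff(levels(arm), small))
  }
  dat <- data.frame(.arm = arm, as.data.frame(x))
  fit <- nnet::multinom(.arm ~ ., data = dat, trace = FALSE,
                        maxit = 1000, reltol = reltol,
                        MaxNWts = 10000)
  cf <- stats::coef(fit)
  if (is.null(dim(cf))) cf <- matrix(cf, nrow = 1,
                                     dimnames = list(levels(arm)[2], names(cf)))
  if (any(abs(cf) > 15)) {
    bad <- unique(colnames(cf)[apply(abs(cf) > 15, 2, any)])
    rlang::abort(paste0("separation detected (diverging coefficients) for: ",
                        paste(bad, collapse = ", ")),
                 class = "oad_separation_error")
  }
  probs <- stats::fitted(fit)
  if (is.null(dim(probs)) || ncol(probs) == 1) {
    probs <- cbind(1 - probs, probs)
    colnames(probs) <- levels(arm)
  }
  structure(
    list(probabilities = probs,
         coefficients = cf,
         arm = arm,
         arm_levels = levels(arm),
         merged = small,
         model = fit),
    class = "oad_propensity"
  )
}

#' Inverse-probability weights from a propensity fit
#'
#' Raw weight `1 / P(observed arm | covariates)` per patient, plus the Hájek
#' (within-arm normalized) weight summing to 1 within each arm. Optional
#' symmetric percentile truncation caps the raw weights before normalization;
#' it is off by default. Probabilities below `floor` are a hard error, with
#' truncation the suggested remedy.
#'
#' @param fit An `oad_propensity`, or a bare n x K probability matrix with arm
#'   labels as column names (e.g. the true assignment probabilities of a
#'   synthetic cohort).
#' @param arm Factor of observed arms; defaults to the fit's own.
#' @param truncate `NULL` (no truncation) or a length-2 probability vector of
#'   percentiles, e.g. `c(0.01, 0.99)`.
#' @param floor Hard lower bound on the observed-arm probability.
#' @return A tibble with `arm`, `prob`, `raw` and `hajek` weights.
#' @export
compute_weights <- function(fit, arm = NULL, truncate = NULL, floor = 1e-6) {
  if (inherits(fit, "oad_propensity")) {
    probs <- fit$probabilities
    if (is.null(arm)) arm <- fit$arm
  } else {
    probs <- as.matrix(fit)
    if (is.null(arm)) rlang::abort("arm required with a bare probability matrix",
                                   class = "oad_validation_error")
  }
  arm <- droplevels(as.factor(arm))
  if (!all(levels(arm) %in% colnames(probs))) {
    rlang::abort("probability matrix lacks columns for some arms",
                 class = "oad_schema_error")
  }
  p_obs <- probs[cbind(seq_along(arm), match(as.character(arm), colnames(probs)))]
  if (any(p_obs < floor)) {
    rlang::abort(paste0("observed-arm probability below ", floor,
                        "; consider weight truncation"),
                 class = "oad_weight_error")
  }
  raw <- 1 / p_obs
  if (!is.null(truncate)) {
    stopifnot(length(truncate) == 2, truncate[1] < truncate[2])
    q <- stats::quantile(raw, truncate)
    raw <- pmin(pmax(raw, q[1]), q[2])
  }
  hajek <- stats::ave(raw, arm, FUN = function(w) w / sum(w))
  tibble::tibble(arm = arm, prob = p_obs, raw = raw, hajek = hajek)
}

#' Inverse-probability-weighted outcome means
#'
#' Per-arm Hájek estimator `sum(w y) / sum(w)` with standard errors from the
#' linearization (Taylor) variance of the ratio estimator:
#' `sqrt(sum(w_i^2 (y_i - est)^2)) / sum(w_i)` within arm. The estimate is
#' invariant to rescaling the weights within an arm; constant weights
#' reproduce the unadjusted subgroup means.
#'
#' @param outcome Numeric outcome vector.
#' @param arm Factor of arm assignments.
#' @param weights Raw (or otherwise positive) weights, e.g. the `raw` column
#'   of [compute_weights()].
#' @param alpha Significance level for letter groups.
#' @param letters Compute letter groups from pairwise z-tests?
#' @return A tibble with `arm`, `n`, `estimate`, `se`, `letters`.
#' @export
weighted_outcomes <- function(outcome, arm, weights, alpha = 0.05,
                              letters = TRUE) {
  arm <- droplevels(as.factor(arm))
  stopifnot(length(outcome) == length(arm), length(weights) == length(arm))
  if (any(weights <= 0)) {
    rlang::abort("weights must be positive", class = "oad_weight_error")
  }
  res <- lapply(levels(arm), function(a) {
    idx <- arm == a
    w <- weights[idx]; y <- outcome[idx]
    est <- sum(w * y) / sum(w)
    se <- sqrt(sum(w^2 * (y - est)^2)) / sum(w)
    tibble::tibble(arm = a, n = sum(idx), estimate = est, se = se)
  })
  out <- dplyr::bind_rows(res)
  if (letters) {
    pmat <- pairwise_z_pvalues(out$estimate, out$se)
    out$letters <- unname(compact_letters(pmat, alpha))
  } else {
    out$letters <- NA_character_
  }
  out
}

#' Weighted covariate balance across arms
#'
#' Weighted per-arm covariate means and a weighted one-way ANOVA p-value per
#' covariate (weighted least squares of the indicator on arm, F-test). With
#' identity weights this reproduces the raw baseline balance table; weights
#' from a correctly specified propensity model pull every arm's means toward
#' the pooled means. Constant covariates get p = 1 by convention.
#'
#' @param covariates Tibble/matrix of covariate indicators.
#' @param arm Factor of arm assignments.
#' @param weights Positive weights.
#' @return A tibble with one row per covariate: per-arm weighted means and
#'   `p_value`.
#' @export
weighted_balance <- function(covariates, arm, weights) {
  x <- covariate_matrix(covariates)
  arm <- droplevels(as.factor(arm))
  stopifnot(nrow(x) == length(arm), length(weights) == length(arm))
  wmean <- function(v, idx) sum(weights[idx] * v[idx]) / sum(weights[idx])
  means <- sapply(levels(arm), function(a) {
    apply(x, 2, wmean, idx = arm == a)
  })
  pvals <- apply(x, 2, function(v) {
    if (stats::var(v) == 0) return(1)
    fit <- stats::lm(v ~ arm, weights = weights)
    tab <- stats::anova(fit)
    p <- tab[["Pr(>F)"]][1]
    if (is.na(p)) 1 else p
  })
  out <- tibble::as_tibble(means)
  dplyr::mutate(out, covariate = colnames(x), p_value = unname(pvals),
                .before = 1)
}
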