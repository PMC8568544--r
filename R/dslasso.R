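#' Build the candidate covariate pool for double selection
#'
#' Expands the binary covariate matrix into the selection pool: all main
#' effects plus the pairwise interaction of every other indicator with the
#' anchor indicator (baseline glycemic control by default). Squared terms of
#' 0/1 indicators are identical to the originals and therefore excluded, as is
#' the anchor's self-interaction. Duplicated and constant columns are dropped
#' deterministically (first occurrence kept), so the full 35-indicator schema
#' yields exactly 69 columns: 35 mains plus 34 interactions.
#'
#' @param covariates Tibble/matrix of binary covariate indicators.
#' @param anchor Name of the interaction anchor column (default
#'   `"hba1c_ctrl_bl"`).
#' @return A numeric matrix with a `provenance` attribute
#'   (`"main"`/`"interaction"` per column).
#' @export
build_candidate_pool <- function(covariates, anchor = "hba1c_ctrl_bl") {
  x <- covariate_matrix(covariates)
  if (!anchor %in% colnames(x)) {
    rlang::abort(paste0("anchor column '", anchor, "' not found"),
                 class = "oad_schema_error")
  }
  if (!all(x %in% c(0, 1))) {
    rlang::abort("candidate pool construction requires binary indicators",
                 class = "oad_validation_error")
  }
  # deterministic dedup of the incoming mains (keep first occurrence)
  x <- x[, !(duplicated(t(x)) | duplicated(colnames(x))), drop = FALSE]
  others <- setdiff(colnames(x), anchor)
  inter <- x[, others, drop = FALSE] * x[, anchor]
  colnames(inter) <- paste0(others, ":", anchor)
  pool <- cbind(x, inter)
  provenance <- c(rep("main", ncol(x)), rep("interaction", ncol(inter)))
  # drop constant columns, then exact duplicates of earlier columns
  keep <- apply(pool, 2, function(v) stats::var(v) > 0)
  pool <- pool[, keep, drop = FALSE]
  provenance <- provenance[keep]
  dup <- duplicated(t(pool))
  pool <- pool[, !dup, drop = FALSE]
  provenance <- provenance[!dup]
  attr(pool, "provenance") <- stats::setNames(provenance, colnames(pool))
  pool
}

#' Adaptive-lasso selection with BIC-tuned penalty
#'
#' L1-penalized least squares with per-coefficient penalty weights
#' `|beta_init|^(-gamma)`, where the pilot `beta_init` is the OLS fit on
#' standardized columns (ridge-initialized when the OLS is rank-deficient).
#' The solution path is computed by coordinate descent over a decreasing
#' penalty grid; the penalty is chosen to minimize the Gaussian BIC
#' `n log(RSS/n) + df log(n)` with `df` the number of nonzero coefficients
#' (ties broken toward the sparser model). Columns are standardized and the
#' response centered internally, so selection is invariant to column order and
#' to affine rescaling of the response.
#'
#' @param response Numeric response vector.
#' @param pool Numeric candidate matrix (e.g. from [build_candidate_pool()]).
#' @param gamma Adaptive-weight exponent (default 1).
#' @param lambda Optional penalty grid; defaults to the coordinate-descent
#'   path's own grid.
#' @param standardize Standardize columns internally (default `TRUE`; set
#'   `FALSE` only for pre-standardized designs).
#' @return List with `selected` (column names with nonzero coefficients at the
#'   chosen penalty), `lambda` (chosen penalty), `beta` (coefficients on the
#'   original scale), `bic_path` (tibble of lambda, df, BIC) and
#'   `penalty_weights`.
#' @export
adaptive_lasso_select <- function(response, pool, gamma = 1, lambda = NULL,
                                  standardize = TRUE) {
  x <- as.matrix(pool)
  stopifnot(nrow(x) == length(response))
  n <- nrow(x); p <- ncol(x)
  y_c <- response - mean(response)
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    rlang::abort("constant columns in the candidate pool",
                 class = "oad_validation_error")
  }
  x_s <- if (standardize) scale(x) else x

  beta_init <- tryCatch({
    fit0 <- stats::lsfit(x_s, y_c, intercept = FALSE)
    b <- fit0$coefficients
    if (any(is.na(b)) || p >= n) stop("rank deficient")
    b
  }, error = function(e) {
    # ridge-initialized pilot when OLS is unavailable
    lam <- 0.01 * sum(diag(crossprod(x_s))) / p
    drop(solve(crossprod(x_s) + diag(lam, p), crossprod(x_s, y_c)))
  })

  w <- pmin(abs(beta_init)^(-gamma), 1e8)
  # pre-normalize so the penalty factors sum to p; the coordinate-descent
  # backend's internal rescaling is then a no-op and thresholds are exact
  w_norm <- w * p / sum(w)

  fit <- glmnet::glmnet(x_s, y_c, family = "gaussian",
                        penalty.factor = w_norm,
                        standardize = FALSE, intercept = FALSE,
                        lambda = lambda, thresh = 1e-7,
                        lambda.min.ratio = if (is.null(lambda)) 1e-4 else NULL)
  lam_grid <- fit$lambda
  betas <- as.matrix(fit$beta)
  pred <- x_s %*% betas
  rss <- colSums((y_c - pred)^2)
  df <- colSums(betas != 0)
  bic <- n * log(rss / n) + df * log(n)
  # minimize BIC; among ties prefer the larger penalty (sparser model)
  best <- order(bic, -lam_grid)[1]
  b_std <- betas[, best]
  b_orig <- if (standardize) b_std / sds else b_std
  list(selected = colnames(x)[b_std != 0],
       lambda = lam_grid[best],
       beta = stats::setNames(b_orig, colnames(x)),
       bic_path = tibble::tibble(lambda = lam_grid, df = as.integer(df),
                                 bic = bic),
       penalty_weights = stats::setNames(w_norm, colnames(x)))
}

#' Double selection of covariates for treatment-effect estimation
#'
#' Runs one adaptive-lasso selection with the outcome as response, then one
#' per non-reference treatment arm with the 0/1 arm indicator as response
#' (linear working model), and takes the union of all selected covariate sets.
#' Controlling for the union guards the treatment-effect estimate against
#' omitted-variable bias from covariates that predict either the outcome or
#' the treatment.
#'
#' @param outcome Numeric outcome vector.
#' @param arm Factor of arm assignments (first level = reference).
#' @param pool Candidate matrix from [build_candidate_pool()].
#' @param gamma Adaptive-weight exponent.
#' @return List with `outcome_selected`, `treatment_selected` (named list per
#'   arm), `union` (in pool column order), and `details` (per-equation
#'   selection objects).
#' @export
double_select <- function(outcome, arm, pool, gamma = 1) {
  arm <- droplevels(as.factor(arm))
  sel_y <- adaptive_lasso_select(outcome, pool, gamma = gamma)
  sel_t <- lapply(levels(arm)[-1], function(a) {
    adaptive_lasso_select(as.numeric(arm == a), pool, gamma = gamma)
  })
  names(sel_t) <- levels(arm)[-1]
  union_set <- colnames(pool)[colnames(pool) %in%
    unique(c(sel_y$selected, unlist(lapply(sel_t, `[[`, "selected"))))]
  list(outcome_selected = sel_y$selected,
       treatment_selected = lapply(sel_t, `[[`, "selected"),
       union = union_set,
       details = c(list(outcome = sel_y), sel_t))
}

#' Post-selection regression and predictive margins
#'
#' Ordinary least squares of the outcome on the treatment dummies plus the
#' union of double-selected covariates, followed by predictive margins with
#' delta-method errors and compact letter groups. An empty union reduces to
#' the arm-dummies-only model, whose margins are the subgroup means.
#'
#' @param outcome Numeric outcome vector.
#' @param arm Factor of arm assignments.
#' @param pool Candidate matrix the selection was run on.
#' @param union Character vector of selected column names (e.g.
#'   `double_select(...)$union`).
#' @param alpha Significance level for letter groups.
#' @return List with `fit` (`oad_lm`) and `margins` (margin tibble).
#' @export
post_selection_fit <- function(outcome, arm, pool, union, alpha = 0.05) {
  bad <- setdiff(union, colnames(pool))
  if (length(bad) > 0) {
    rlang::abort(paste0("selected columns not in pool: ",
                        paste(bad, collapse = ", ")),
                 class = "oad_schema_error")
  }
  covs <- if (length(union) > 0) pool[, union, drop = FALSE] else NULL
  fit <- fit_outcome_model(outcome, arm, covs)
  margins <- predictive_margins(fit, alpha = alpha)
  list(fit = fit, margins = margins)
}
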