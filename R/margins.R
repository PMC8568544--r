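#' Fit the multivariate linear outcome model
#'
#' Ordinary least squares of an outcome on the seven treatment dummies
#' (reference arm Metformin) and any baseline covariates, with classical
#' (homoskedastic) standard errors by default. Every outcome — binary control,
#' hypoglycemia count, utility and costs — is fit in the same linear
#' framework, so each arm coefficient is the adjusted mean difference versus
#' the reference arm.
#'
#' @param outcome Numeric outcome vector.
#' @param arm Factor of arm assignments; the first level present is the
#'   reference.
#' @param covariates Optional tibble/matrix of covariate columns (a
#'   `patient_id` column is ignored). `NULL` fits arm dummies only.
#' @param robust Use heteroskedasticity-robust (HC1) coefficient covariance
#'   instead of the classical one.
#' @return An object of class `oad_lm`: list with `model` (the underlying
#'   [stats::lm()] fit), `coefficients` tibble (estimate, se, p-value,
#'   significance stars at 0.10/0.05/0.01), `vcov`, `arm_levels`,
#'   `covariate_names`, `n`.
#' @export
fit_outcome_model <- function(outcome, arm, covariates = NULL,
                              robust = FALSE) {
  arm <- droplevels(as.factor(arm))
  dat <- data.frame(.y = outcome, .arm = arm)
  covnames <- character(0)
  if (!is.null(covariates)) {
    x <- covariate_matrix(covariates)
    covnames <- colnames(x)
    dat <- cbind(dat, as.data.frame(x))
  }
  if (nrow(dat) <= ncol(dat)) {
    rlang::abort("need more observations than model columns",
                 class = "oad_validation_error")
  }
  fit <- stats::lm(.y ~ ., data = dat)
  aliased <- is.na(stats::coef(fit))
  if (any(aliased)) {
    rlang::abort(paste0("collinear design; aliased columns: ",
                        paste(names(which(aliased)), collapse = ", ")),
                 class = "oad_rank_error")
  }
  V <- if (robust) hc1_vcov(fit) else stats::vcov(fit)
  beta <- stats::coef(fit)
  se <- sqrt(diag(V))
  pval <- 2 * stats::pt(-abs(beta / se), df = fit$df.residual)
  stars <- cut(pval, c(-Inf, 0.01, 0.05, 0.10, Inf),
               labels = c("***", "**", "*", ""))
  structure(
    list(model = fit,
         coefficients = tibble::tibble(term = names(beta),
                                       estimate = unname(beta),
                                       se = unname(se),
                                       p_value = unname(pval),
                                       stars = as.character(stars)),
         vcov = V,
         arm_levels = levels(arm),
         covariate_names = covnames,
         robust = robust,
         n = nrow(dat)),
    class = "oad_lm"
  )
}

# HC1 sandwich covariance for an lm fit
hc1_vcov <- function(fit) {
  X <- stats::model.matrix(fit)
  u <- stats::residuals(fit)
  n <- nrow(X); p <- ncol(X)
  XtXinv <- chol2inv(chol(crossprod(X)))
  meat <- crossprod(X * u)
  n / (n - p) * XtXinv %*% meat %*% XtXinv
}

#' @export
print.oad_lm <- function(x, ...) {
  cat("Linear outcome model (", x$n, " patients, reference arm ",
      x$arm_levels[1], ")\n", sep = "")
  print(x$coefficients, n = Inf)
  invisible(x)
}

#' Predictive margins by G-computation with delta-method errors
#'
#' For each therapy arm, sets every patient's treatment to that arm, predicts
#' the outcome from the fitted linear model with the patient's own covariates,
#' and averages the predictions over the sample. For a linear model this
#' equals the prediction at the average design row, so
#' `margin(arm) - margin(reference)` is exactly the arm coefficient, and with
#' no covariates the margins are exactly the subgroup means. Standard errors
#' come from the delta method: `se_k = sqrt(g_k' V g_k)` with `g_k` the
#' averaged design row under arm `k` and `V` the coefficient covariance; the
#' full margin covariance is retained so the letter display accounts for
#' shared coefficient uncertainty. Covariate means are treated as fixed.
#'
#' @param fit An `oad_lm` from [fit_outcome_model()].
#' @param covariates Covariate rows to average over; defaults to the
#'   estimation sample.
#' @param alpha Significance level for letter groups.
#' @return A tibble with `arm`, `margin`, `se`, `letters`; the margin
#'   covariance matrix is attached as attribute `"vcov"`.
#' @export
predictive_margins <- function(fit, covariates = NULL, alpha = 0.05) {
  stopifnot(inherits(fit, "oad_lm"))
  beta <- stats::coef(fit$model)
  terms_all <- names(beta)
  if (is.null(covariates)) {
    xbar <- colMeans(stats::model.matrix(fit$model))
  } else {
    x <- covariate_matrix(covariates)
    missing_cols <- setdiff(fit$covariate_names, colnames(x))
    if (length(missing_cols) > 0) {
      rlang::abort(paste0("covariate rows missing columns used in fit: ",
                          paste(missing_cols, collapse = ", ")),
                   class = "oad_schema_error")
    }
    xbar <- stats::setNames(numeric(length(terms_all)), terms_all)
    xbar["(Intercept)"] <- 1
    xbar[fit$covariate_names] <- colMeans(x[, fit$covariate_names, drop = FALSE])
  }
  arms <- fit$arm_levels
  G <- matrix(0, length(arms), length(terms_all),
              dimnames = list(arms, terms_all))
  for (a in arms) {
    g <- xbar
    g[startsWith(names(g), ".arm")] <- 0
    if (a != arms[1]) g[paste0(".arm", a)] <- 1
    G[a, ] <- g
  }
  margin <- drop(G %*% beta)
  V <- G %*% fit$vcov %*% t(G)
  se <- sqrt(diag(V))
  pmat <- margin_pvalues(margin, V)
  out <- tibble::tibble(arm = arms, margin = unname(margin),
                        se = unname(se),
                        letters = unname(compact_letters(pmat, alpha)))
  attr(out, "vcov") <- V
  out
}

# pairwise z-tests on margins using the full margin covariance
margin_pvalues <- function(margin, V) {
  k <- length(margin)
  p <- matrix(1, k, k, dimnames = list(names(margin), names(margin)))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i < j) {
        vd <- V[i, i] + V[j, j] - 2 * V[i, j]
        z <- if (vd <= 0) 0 else abs(margin[i] - margin[j]) / sqrt(vd)
        p[i, j] <- p[j, i] <- 2 * stats::pnorm(-z)
      }
    }
  }
  p
}
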