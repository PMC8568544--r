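#' Pairwise two-sample z-test p-values from group estimates
#'
#' Unadjusted two-sided p-values for every pair of groups, computed from the
#' estimates and their standard errors as
#' `2 * pnorm(-|m_i - m_j| / sqrt(se_i^2 + se_j^2))`. No multiplicity
#' correction is applied unless requested.
#'
#' @param estimate Numeric vector of group estimates.
#' @param se Numeric vector of standard errors (same length).
#' @param adjust Multiplicity adjustment passed to [stats::p.adjust()]
#'   (default `"none"`; `"bonferroni"` available).
#' @return A symmetric matrix of p-values with 1 on the diagonal.
#' @export
pairwise_z_pvalues <- function(estimate, se, adjust = "none") {
  k <- length(estimate)
  stopifnot(length(se) == k)
  p <- matrix(1, k, k, dimnames = list(names(estimate), names(estimate)))
  if (k < 2) return(p)
  pairs <- utils::combn(k, 2)
  z <- abs(estimate[pairs[1, ]] - estimate[pairs[2, ]]) /
    sqrt(se[pairs[1, ]]^2 + se[pairs[2, ]]^2)
  pv <- stats::p.adjust(2 * stats::pnorm(-z), method = adjust)
  for (i in seq_len(ncol(pairs))) {
    p[pairs[1, i], pairs[2, i]] <- pv[i]
    p[pairs[2, i], pairs[1, i]] <- pv[i]
  }
  p
}

#' Compact letter display by insert-and-absorb
#'
#' Assigns lower-case letters to groups so that two groups share at least one
#' letter if and only if their pairwise p-value is at or above `alpha`.
#' The insert-and-absorb construction starts from a single letter covering all
#' groups; each significant pair splits every letter column containing both
#' members into two columns (one without each member), and columns whose group
#' set is contained in another's are absorbed. Non-transitive significance
#' patterns are representable through overlapping letters and are never an
#' error. Letters are ordered by first group position, making the display
#' deterministic.
#'
#' @param p Symmetric matrix of pairwise p-values.
#' @param alpha Significance level (default 0.05).
#' @return Character vector of letter strings, one per group (named when `p`
#'   has dimnames).
#' @export
compact_letters <- function(p, alpha = 0.05) {
  stopifnot(is.matrix(p), nrow(p) == ncol(p))
  k <- nrow(p)
  if (k == 0) return(character(0))
  # columns of the display, each a logical membership vector over groups
  cols <- list(rep(TRUE, k))
  if (k > 1) {
    for (i in seq_len(k - 1)) {
      for (j in seq(i + 1, k)) {
        if (p[i, j] < alpha) {
          new_cols <- list()
          for (cc in cols) {
            if (cc[i] && cc[j]) {
              c1 <- cc; c1[i] <- FALSE
              c2 <- cc; c2[j] <- FALSE
              new_cols <- c(new_cols, list(c1, c2))
            } else {
              new_cols <- c(new_cols, list(cc))
            }
          }
          # absorb: drop empty and duplicated columns, then any column whose
          # group set is a proper subset of another's
          new_cols <- new_cols[vapply(new_cols, any, logical(1))]
          key <- vapply(new_cols, function(cc) paste(which(cc), collapse = ","),
                        character(1))
          new_cols <- new_cols[!duplicated(key)]
          keep <- vapply(seq_along(new_cols), function(a) {
            !any(vapply(seq_along(new_cols), function(b) {
              b != a && all(new_cols[[a]] <= new_cols[[b]])
            }, logical(1)))
          }, logical(1))
          cols <- new_cols[keep]
        }
      }
    }
  }
  # order columns by first member for a deterministic letter sequence
  first <- vapply(cols, function(cc) which(cc)[1], integer(1))
  cols <- cols[order(first)]
  letters_seq <- c(letters, paste0(rep(letters, each = 26), letters))
  out <- vapply(seq_len(k), function(g) {
    paste0(letters_seq[which(vapply(cols, `[`, logical(1), g))], collapse = "")
  }, character(1))
  names(out) <- rownames(p)
  out
}

#' Unadjusted subgroup summary with letter groups
#'
#' Per-arm means with standard errors: for a continuous outcome
#' `SE = sd / sqrt(n)`; for a binary outcome the binomial form
#' `sqrt(p (1 - p) / n)`. Arms with no patients are omitted; an arm with a
#' single patient gets `NA` standard error and is flagged with a warning.
#' Letter groups come from unadjusted pairwise z-tests at level `alpha`
#' via [compact_letters()].
#'
#' @param outcome Numeric outcome vector.
#' @param arm Factor of arm assignments (same length).
#' @param type `"continuous"` or `"binary"`.
#' @param alpha Significance level for the letter display.
#' @param letters Compute letter groups? (Skipped when any SE is `NA`.)
#' @return A tibble with `arm`, `n`, `estimate`, `se`, `letters`.
#' @export
subgroup_summary <- function(outcome, arm,
                             type = c("continuous", "binary"),
                             alpha = 0.05, letters = TRUE) {
  type <- match.arg(type)
  stopifnot(length(outcome) == length(arm))
  if (any(!is.finite(outcome))) {
    rlang::abort("outcome contains missing values",
                 class = "oad_missing_data_error")
  }
  arm <- droplevels(as.factor(arm))
  n <- as.integer(table(arm))
  est <- tapply(outcome, arm, mean)
  if (type == "binary") {
    if (!all(outcome %in% c(0, 1))) {
      rlang::abort("binary outcome must be 0/1", class = "oad_validation_error")
    }
    se <- sqrt(est * (1 - est) / n)
  } else {
    sdv <- tapply(outcome, arm, stats::sd)
    se <- sdv / sqrt(n)
    if (any(n == 1)) {
      rlang::warn("arm with a single patient: standard error undefined",
                  class = "oad_degenerate_arm")
    }
  }
  out <- tibble::tibble(arm = levels(arm), n = n,
                        estimate = as.numeric(est), se = as.numeric(se))
  if (letters && !any(is.na(out$se))) {
    pmat <- pairwise_z_pvalues(out$estimate, out$se)
    out$letters <- unname(compact_letters(pmat, alpha))
  } else {
    out$letters <- NA_character_
  }
  attr(out, "alpha") <- alpha
  out
}

#' One-way ANOVA balance test for a covariate across arms
#'
#' F-test p-value from a one-way analysis of variance treating the (typically
#' 0/1) covariate as numeric — the conventional balance check for baseline
#' characteristics across treatment arms. When every group has zero
#' within-group variance and all group means agree (e.g. a constant
#' covariate), the p-value is 1 by convention.
#'
#' @param x Numeric covariate vector.
#' @param arm Factor of arm assignments.
#' @return The ANOVA F-test p-value.
#' @export
anova_balance <- function(x, arm) {
  arm <- droplevels(as.factor(arm))
  if (nlevels(arm) < 2 || any(table(arm) < 2)) {
    rlang::abort("need at least two arms with at least two patients each",
                 class = "oad_validation_error")
  }
  if (stats::var(x) == 0) return(1)
  fit <- stats::aov(x ~ arm)
  tab <- summary(fit)[[1]]
  p <- tab[["Pr(>F)"]][1]
  if (is.na(p)) 1 else p
}

#' Baseline balance table across arms
#'
#' Per-arm means of every covariate indicator with the whole-sample mean and
#' the one-way ANOVA balance p-value per row.
#'
#' @param covariates Tibble or matrix of covariate indicators (a
#'   `patient_id` column is ignored).
#' @param arm Factor of arm assignments.
#' @return A tibble with one row per covariate: per-arm means, `total`, and
#'   `p_value`.
#' @export
balance_table <- function(covariates, arm) {
  x <- covariate_matrix(covariates)
  arm <- droplevels(as.factor(arm))
  means <- apply(x, 2, function(v) tapply(v, arm, mean))
  # the F-test needs at least two patients per arm; single-patient arms are
  # still described but excluded from the test
  tab <- table(arm)
  testable <- arm %in% names(tab)[tab >= 2]
  arm_test <- droplevels(arm[testable])
  out <- tibble::as_tibble(t(means))
  out <- dplyr::mutate(out,
                       covariate = colnames(x),
                       total = colMeans(x),
                       p_value = unname(apply(x[testable, , drop = FALSE], 2,
                                              anova_balance, arm = arm_test)),
                       .before = 1)
  out
}

# accept tibble (with optional patient_id) or matrix; return numeric matrix
covariate_matrix <- function(covariates) {
  if (is.matrix(covariates)) return(covariates)
  covariates <- as.data.frame(covariates)
  covariates$patient_id <- NULL
  as.matrix(covariates)
}
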