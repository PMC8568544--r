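test_that("two-arm propensity fit matches binary logistic regression", {
  set.seed(31)
  n <- 400
  x <- cbind(a = stats::rbinom(n, 1, 0.5), b = stats::rbinom(n, 1, 0.3))
  eta <- -0.3 + 0.8 * x[, "a"] - 0.5 * x[, "b"]
  arm <- factor(ifelse(stats::runif(n) < stats::plogis(eta), "B", "A"))
  fit <- fit_propensity(arm, x, min_arm_n = 2)
  glm_fit <- stats::glm(arm == "B" ~ x, family = stats::binomial())
  expect_equal(unname(fit$coefficients["B", ]),
               unname(stats::coef(glm_fit)), tolerance = 1e-4)
  expect_equal(unname(fit$probabilities[, "B"]),
               unname(stats::fitted(glm_fit)), tolerance = 1e-5)
})

test_that("multinomial fit attains the grid-search likelihood maximum", {
  # toy 3-arm, 1-covariate problem: profile the log-likelihood on a grid
  set.seed(32)
  n <- 300
  x <- cbind(z = stats::rbinom(n, 1, 0.5))
  p <- cbind(0.5, 0.25 + 0.15 * x[, 1], 0.25 - 0.15 * x[, 1])
  arm <- factor(apply(p, 1, function(pr) sample(c("A", "B", "C"), 1, prob = pr)),
                levels = c("A", "B", "C"))
  fit <- fit_propensity(arm, x, min_arm_n = 2)
  loglik <- function(b) {
    # b = (int_B, z_B, int_C, z_C), reference arm A
    eta_b <- b[1] + b[2] * x[, 1]
    eta_c <- b[3] + b[4] * x[, 1]
    den <- 1 + exp(eta_b) + exp(eta_c)
    sum(ifelse(arm == "B", eta_b, ifelse(arm == "C", eta_c, 0)) - log(den))
  }
  ll_fit <- loglik(c(fit$coefficients["B", ], fit$coefficients["C", ]))
  grid <- expand.grid(ib = seq(-1.5, 1.5, by = 0.25),
                      zb = seq(-1.5, 1.5, by = 0.25),
                      ic = seq(-1.5, 1.5, by = 0.25),
                      zc = seq(-1.5, 1.5, by = 0.25))
  ll_grid <- apply(grid, 1, loglik)
  expect_gte(ll_fit, max(ll_grid) - 1e-6)
})

test_that("covariates unrelated to assignment give near-null coefficients", {
  set.seed(33)
  n <- 2500
  x <- cbind(a = stats::rbinom(n, 1, 0.4), b = stats::rbinom(n, 1, 0.6))
  arm <- factor(sample(c("A", "B", "C"), n, replace = TRUE,
                       prob = c(0.5, 0.3, 0.2)))
  fit <- fit_propensity(arm, x, min_arm_n = 2)
  expect_true(all(abs(fit$coefficients[, c("a", "b")]) < 0.25))
  expect_equal(unname(colMeans(fit$probabilities)),
               as.numeric(table(arm) / n), tolerance = 0.01)
})

test_that("small arms are merged before propensity fitting", {
  co <- generate_cohort(sim_config(seed = 4))
  arm <- define_cohorts(co)$arm
  cv <- build_covariates(co)
  fit <- fit_propensity(arm, cv)
  expect_true("Glibenclamide" %in% fit$merged)
  expect_false("Glibenclamide" %in% fit$arm_levels)
  expect_equal(unname(rowSums(fit$probabilities)), rep(1, nrow(co)),
               tolerance = 1e-8)
})

test_that("weights are reciprocals, normalized within arm", {
  probs <- matrix(c(0.5, 0.25, 0.25,
                    0.2, 0.5, 0.3,
                    0.25, 0.25, 0.5,
                    0.4, 0.4, 0.2), 4, 3, byrow = TRUE,
                  dimnames = list(NULL, c("A", "B", "C")))
  arm <- factor(c("A", "B", "C", "A"))
  w <- compute_weights(probs, arm)
  expect_equal(w$raw, c(1 / 0.5, 1 / 0.5, 1 / 0.5, 1 / 0.4))
  # Hajek weights sum to one within each arm
  expect_equal(as.numeric(tapply(w$hajek, w$arm, sum)), c(1, 1, 1))
  expect_equal(w$hajek[2], 1)  # single-patient arm gets full weight
  # probability floor is a hard error
  probs2 <- probs; probs2[1, "A"] <- 1e-9
  expect_error(compute_weights(probs2, arm), class = "oad_weight_error")
})

test_that("weighted means match hand computation and scaling invariance", {
  y <- c(2, 4, 6, 8)
  arm <- factor(rep("A", 4))
  w <- c(2, 1, 1, 2)
  out <- weighted_outcomes(y, arm, w, letters = FALSE)
  expect_equal(out$estimate, (2 * 2 + 4 + 6 + 8 * 2) / 6)
  se_oracle <- sqrt(sum(w^2 * (y - out$estimate)^2)) / sum(w)
  expect_equal(out$se, se_oracle)
  # invariant to within-arm rescaling of the weights
  out2 <- weighted_outcomes(y, arm, 10 * w, letters = FALSE)
  expect_equal(out2$estimate, out$estimate)
  # constant weights reproduce unadjusted subgroup means
  y2 <- stats::rnorm(30)
  arm2 <- factor(rep(c("A", "B", "C"), 10))
  out3 <- weighted_outcomes(y2, arm2, rep(1, 30), letters = FALSE)
  expect_equal(out3$estimate, as.numeric(tapply(y2, arm2, mean)[out3$arm]))
})

test_that("true-propensity weighting removes confounding in the mean", {
  # single cohort, large n: weighted arm means approach configured truth
  cfg <- sim_config(n_patients = 20000, seed = 35)
  co <- generate_cohort(cfg)
  truth <- cohort_truth(co)
  arm <- define_cohorts(co)$arm
  oc <- derive_outcomes(co)
  w <- compute_weights(truth$propensity, arm)
  out <- weighted_outcomes(oc$hba1c_control, arm, w$raw, letters = FALSE)
  big <- out$arm[out$n > 800]
  expect_true(all(abs(out$estimate[out$arm %in% big] -
                        truth$margins[big, "hba1c_control"]) < 0.03))
  # the unadjusted mean of the most confounded arm (herbal TCM users,
  # concentrated in Shenyang with worse baseline glycemia) stays biased
  raw_mean <- mean(oc$hba1c_control[arm == "Other TCMs"])
  expect_lt(raw_mean - truth$margins["Other TCMs", "hba1c_control"], -0.03)
})

test_that("weighted balance diagnostics behave at the identity and in truth", {
  co <- generate_cohort(sim_config(n_patients = 2000, seed = 36))
  arm <- define_cohorts(co)$arm
  cv <- build_covariates(co)
  # identity weights reproduce the raw balance table
  wb1 <- weighted_balance(cv, arm, rep(1, nrow(co)))
  raw <- balance_table(cv, arm)
  expect_equal(wb1$Metformin, raw$Metformin, tolerance = 1e-12)
  expect_equal(wb1$p_value, raw$p_value, tolerance = 1e-9)
  # true-propensity weights pull arm means toward the pooled means
  truth <- cohort_truth(co)
  w <- compute_weights(truth$propensity, arm)
  wb2 <- weighted_balance(cv, arm, w$raw)
  pooled <- colMeans(as.matrix(cv[-1]))
  gap_w <- abs(wb2[["Other TCMs"]] - pooled)
  gap_r <- abs(raw[["Other TCMs"]] - pooled)
  # the covariate most loaded into TCM assignment is city of residence
  i <- which(wb2$covariate == "city_shenyang")
  expect_lt(gap_w[i], gap_r[i])
  # constant covariate gets p = 1
  cvc <- cbind(as.matrix(cv[-1]), const = 1)
  wb3 <- weighted_balance(cvc, arm, w$raw)
  expect_equal(wb3$p_value[wb3$covariate == "const"], 1)
})
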