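test_that("candidate pool has mains plus anchor interactions", {
  co <- generate_cohort(sim_config(n_patients = 800, seed = 41))
  cv <- build_covariates(co)
  pool <- build_candidate_pool(cv)
  expect_equal(ncol(pool), 69)
  prov <- attr(pool, "provenance")
  expect_equal(sum(prov == "main"), 35)
  expect_equal(sum(prov == "interaction"), 34)
  # the anchor's self-interaction is excluded
  expect_false("hba1c_ctrl_bl:hba1c_ctrl_bl" %in% colnames(pool))
  # interaction columns are the elementwise products
  expect_equal(pool[, "smoking:hba1c_ctrl_bl"],
               pool[, "smoking"] * pool[, "hba1c_ctrl_bl"])

  # minimal schema {A, anchor} gives a pool of 3
  x <- cbind(A = c(0, 1, 0, 1, 1, 0), hba1c_ctrl_bl = c(1, 1, 0, 0, 1, 0))
  p3 <- build_candidate_pool(x)
  expect_equal(ncol(p3), 3)
  expect_setequal(colnames(p3), c("A", "hba1c_ctrl_bl", "A:hba1c_ctrl_bl"))

  # duplicated input columns appear once
  xd <- cbind(A = c(0, 1, 0, 1), B = c(0, 1, 0, 1),
              hba1c_ctrl_bl = c(1, 0, 1, 1))
  pd <- build_candidate_pool(xd)
  expect_false("B" %in% colnames(pd))

  # non-binary columns are rejected
  xb <- cbind(A = c(0.5, 1, 0, 1), hba1c_ctrl_bl = c(1, 0, 1, 1))
  expect_error(build_candidate_pool(xb), class = "oad_validation_error")
})

test_that("penalty limits select everything and nothing", {
  set.seed(42)
  n <- 120
  x <- matrix(stats::rbinom(n * 5, 1, 0.5), n, 5,
              dimnames = list(NULL, paste0("x", 1:5)))
  y <- 0.8 * x[, 1] - 0.6 * x[, 3] + stats::rnorm(n, 0, 0.4)
  sel0 <- suppressWarnings(
    adaptive_lasso_select(y, x, lambda = c(1e-4, 1e-8)))
  expect_setequal(sel0$selected, paste0("x", 1:5))  # all nonzero OLS coefs
  selinf <- suppressWarnings(
    adaptive_lasso_select(y, x, lambda = c(1e4, 1e3)))
  expect_length(selinf$selected, 0)
})

test_that("orthonormal designs match closed-form soft-thresholding", {
  set.seed(43)
  n <- 64
  # exactly centered, exactly orthogonal columns with unit sample variance:
  # QR of a column-centered matrix, rescaled so crossprod(q) = (n-1) I
  x0 <- scale(matrix(stats::rnorm(n * 6), n, 6), center = TRUE, scale = FALSE)
  q <- qr.Q(qr(x0)) * sqrt(n - 1)
  colnames(q) <- paste0("v", 1:6)
  beta_true <- c(1.2, 0, 0.6, 0, 0.25, 0)
  y <- drop(q %*% beta_true) + stats::rnorm(n, 0, 0.3)
  y_c <- y - mean(y)
  ols <- drop(crossprod(q, y_c)) / (n - 1)
  w <- pmin(abs(ols)^(-1), 1e8)
  w_norm <- w * 6 / sum(w)
  for (lam in c(0.01, 0.05, 0.15)) {
    sel <- suppressWarnings(
      adaptive_lasso_select(y, q, gamma = 1, lambda = lam,
                            standardize = FALSE))
    # penalized objective (1/2n)RSS + lam * sum(w_j |b_j|): with
    # crossprod = (n-1) I the solution is coordinatewise soft-thresholding
    # of the OLS coefficient at lam * w_j * n / (n - 1)
    thr <- lam * w_norm * n / (n - 1)
    oracle <- sign(ols) * pmax(abs(ols) - thr, 0)
    expect_equal(unname(sel$beta), unname(oracle), tolerance = 1e-4)
    expect_setequal(sel$selected, colnames(q)[oracle != 0])
  }
})

test_that("BIC tuning matches a direct path recomputation", {
  set.seed(44)
  n <- 200
  x <- matrix(stats::rbinom(n * 10, 1, 0.4), n, 10,
              dimnames = list(NULL, paste0("x", 1:10)))
  y <- 1.0 * x[, 2] - 0.8 * x[, 7] + stats::rnorm(n, 0, 0.5)
  sel <- adaptive_lasso_select(y, x)
  path <- sel$bic_path
  expect_equal(path$bic,
               n * log({
                 xs <- scale(x); yc <- y - mean(y)
                 # recompute RSS at each stored lambda from a fresh fit
                 refit <- glmnet::glmnet(xs, yc,
                                         penalty.factor = sel$penalty_weights,
                                         standardize = FALSE, intercept = FALSE,
                                         lambda = path$lambda, thresh = 1e-7)
                 colSums((yc - xs %*% as.matrix(refit$beta))^2)
               } / n) + path$df * log(n),
               tolerance = 1e-6)
  expect_equal(sel$lambda, path$lambda[which.min(path$bic)])
  # the informative covariates are selected
  expect_true(all(c("x2", "x7") %in% sel$selected))
})

test_that("selection is invariant to column order and response scaling", {
  set.seed(45)
  n <- 150
  x <- matrix(stats::rbinom(n * 8, 1, 0.5), n, 8,
              dimnames = list(NULL, paste0("x", 1:8)))
  y <- 0.9 * x[, 1] + 0.5 * x[, 5] + stats::rnorm(n, 0, 0.4)
  s1 <- adaptive_lasso_select(y, x)
  s2 <- adaptive_lasso_select(y, x[, sample(8)])
  expect_setequal(s1$selected, s2$selected)
  s3 <- adaptive_lasso_select(3 * y + 10, x)
  expect_setequal(s1$selected, s3$selected)
})

test_that("double selection unions outcome and treatment predictors", {
  set.seed(46)
  n <- 1200
  x <- matrix(stats::rbinom(n * 10, 1, 0.5), n, 10,
              dimnames = list(NULL, paste0("x", 1:10)))
  # x3 confounds assignment only, x5 affects the outcome only
  p_b <- stats::plogis(-1 + 1.5 * x[, 3])
  arm <- factor(ifelse(stats::runif(n) < p_b, "B", "A"), levels = c("A", "B"))
  y <- 0.5 * (arm == "B") + 1.2 * x[, 5] + stats::rnorm(n, 0, 0.5)
  ds <- double_select(y, arm, x)
  expect_true("x5" %in% ds$outcome_selected)
  expect_true("x3" %in% ds$treatment_selected$B)
  expect_true(all(c("x3", "x5") %in% ds$union))
  expect_true(all(ds$union %in% colnames(x)))
  expect_true(all(ds$outcome_selected %in% ds$union))
})

test_that("post-selection nesting identities hold", {
  co <- generate_cohort(sim_config(n_patients = 600, seed = 47))
  arm <- define_cohorts(co)$arm
  oc <- derive_outcomes(co)
  cv <- build_covariates(co)
  pool <- build_candidate_pool(cv)
  # union = all mains reproduces the fully adjusted model
  mains <- colnames(pool)[attr(pool, "provenance") == "main"]
  post_full <- post_selection_fit(oc$hba1c_control, arm, pool, mains)
  fit_ref <- fit_outcome_model(oc$hba1c_control, arm, as.matrix(cv[-1]))
  m_ref <- predictive_margins(fit_ref)
  expect_equal(post_full$margins$margin, m_ref$margin, tolerance = 1e-10)
  # empty union gives subgroup means
  post_empty <- post_selection_fit(oc$hba1c_control, arm, pool, character(0))
  means <- tapply(oc$hba1c_control, arm, mean)
  expect_equal(post_empty$margins$margin,
               as.numeric(means[post_empty$margins$arm]), tolerance = 1e-10)
  expect_error(post_selection_fit(oc$hba1c_control, arm, pool, "nope"),
               class = "oad_schema_error")
})
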