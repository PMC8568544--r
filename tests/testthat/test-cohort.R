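test_that("covariate indicators apply the clinical cutoffs", {
  co <- toy_cohort(1, age_years = 65, hba1c = 6.1, sbp = 150)
  cv <- build_covariates(co)
  expect_equal(cv$age_60_70, 1L)
  expect_equal(cv$age_50_60, 0L)
  expect_equal(cv$hba1c_ctrl_bl, 1L)
  expect_equal(cv$sbp_ge140, 1L)

  # boundary: TG exactly at the 1.7 mmol/L cutoff counts as elevated
  cv2 <- build_covariates(toy_cohort(1, tg = 1.7))
  expect_equal(cv2$tg_ge17, 1L)
  expect_equal(build_covariates(toy_cohort(1, tg = 1.6999))$tg_ge17, 0L)

  # reference categories are all-zero within their dummy group
  cv3 <- build_covariates(toy_cohort(1, age_years = 45, city = "Beijing"))
  expect_true(all(cv3[c("age_50_60", "age_60_70", "age_70plus")] == 0))
  expect_true(all(cv3[c("city_shenyang", "city_chengdu", "city_nanjing",
                        "city_guangzhou")] == 0))

  expect_equal(ncol(cv) - 1L, 35L)
  expect_identical(names(cv)[-1], covariate_names())
})

test_that("dummy groups are mutually exclusive for every generated patient", {
  co <- generate_cohort(sim_config(n_patients = 400, seed = 11))
  cv <- build_covariates(co)
  groups <- list(c("age_50_60", "age_60_70", "age_70plus"),
                 c("edu_lower_sec", "edu_upper_sec", "edu_tertiary"),
                 c("city_shenyang", "city_chengdu", "city_nanjing",
                   "city_guangzhou"),
                 c("income_mid", "income_high"),
                 c("ins_uebmi", "ins_nrcm", "ins_gov"),
                 c("duration_5_10", "duration_10plus"))
  for (g in groups) {
    expect_true(all(rowSums(cv[g]) <= 1))
  }
  expect_true(all(as.matrix(cv[-1]) %in% 0:1))
})

test_that("missing baseline measures raise an explicit error", {
  co <- toy_cohort(2)
  co$fbs[2] <- NA
  expect_error(build_covariates(co), class = "oad_missing_data_error")
  expect_error(validate_cohort(toy_cohort(1, cost_otc = -0.5)),
               class = "oad_validation_error")
})

test_that("therapy classification maps plans to the eight arms", {
  expect_equal(as.character(classify_therapy("metformin")), "Metformin")
  expect_equal(as.character(classify_therapy("Xiaoke Pill")), "Xiaoke Pill")
  expect_equal(as.character(classify_therapy("TCMs")), "Other TCMs")
  expect_equal(as.character(classify_therapy("gliclazide")), "Gliclazide")
  expect_equal(as.character(classify_therapy("acarbose")), "Acarbose")
  expect_equal(as.character(classify_therapy("glibenclamide")), "Glibenclamide")
  # any multi-drug plan containing the Xiaoke Pill is the combination arm
  expect_equal(as.character(classify_therapy("Xiaoke Pill;metformin")),
               "Xiaoke Pill+")
  expect_equal(as.character(classify_therapy("acarbose;Xiaoke Pill;TCMs")),
               "Xiaoke Pill+")
  # all other combinations and minor monotherapies pool into Others
  expect_equal(as.character(classify_therapy("gliclazide;metformin")), "Others")
  expect_equal(as.character(classify_therapy("glipizide")), "Others")
  expect_equal(as.character(classify_therapy("metformin;TCMs")), "Others")
  # case-insensitive dictionary matching
  expect_equal(as.character(classify_therapy("METFORMIN")), "Metformin")
  expect_error(classify_therapy(list(character(0))),
               class = "oad_classification_error")
  expect_error(classify_therapy("insulin"),
               class = "oad_classification_error")
  expect_warning(out <- classify_therapy("sitagliptin"),
                 class = "oad_unknown_drug")
  expect_equal(as.character(out), "Others")
})

test_that("classification is total over all observed multi-drug plan shapes", {
  agents <- c("metformin", "phenformin", "glibenclamide", "glipizide",
              "gliquidone", "gliclazide", "glimepiride", "acarbose",
              "voglibose", "repaglinide", "nateglinide", "rosiglitazone",
              "pioglitazone", "TCMs", "Xiaoke Pill")
  pairs <- utils::combn(agents, 2, simplify = FALSE)
  arms <- classify_therapy(pairs)
  expect_false(anyNA(arms))
  with_xkp <- vapply(pairs, function(p) "Xiaoke Pill" %in% p, logical(1))
  expect_true(all(arms[with_xkp] == "Xiaoke Pill+"))
  expect_true(all(arms[!with_xkp] == "Others"))
})

test_that("ITT and on-treatment cohorts follow the adherence rule", {
  co <- toy_cohort(3)
  co$drugs_fu3[2] <- "metformin;acarbose"    # add-on at wave 3
  co$drugs_fu1[3] <- "gliclazide"            # switch at wave 1
  out <- define_cohorts(co)
  expect_equal(as.character(out$arm), rep("Metformin", 3))
  expect_equal(out$adherent, c(TRUE, FALSE, FALSE))

  # brute-force adherence count over a mixed toy cohort
  co2 <- toy_cohort(10)
  nonadh <- c(2, 5, 7, 10)
  for (i in nonadh) co2$drugs_fu4[i] <- "metformin;acarbose"
  out2 <- define_cohorts(co2)
  expect_equal(sum(out2$adherent), 6)
  # order of drug names within a plan does not matter
  co3 <- toy_cohort(1, drugs_baseline = "metformin;acarbose",
                    drugs_fu1 = "acarbose;metformin",
                    drugs_fu2 = "metformin;acarbose",
                    drugs_fu3 = "acarbose;metformin",
                    drugs_fu4 = "metformin;acarbose")
  expect_true(define_cohorts(co3)$adherent)
})

test_that("outcome derivation applies the strict control cutoff and sums", {
  co <- toy_cohort(3,
                   endpoint_hba1c = c(6.49, 6.5, 7.2),
                   hypo_fu1 = c(1, 0, 0), hypo_fu2 = c(0, 0, 1),
                   hypo_fu3 = c(1, 0, 1), hypo_fu4 = c(0, 0, 1),
                   cost_inpatient = c(4.22, 0, 1),
                   cost_outpatient = c(3.13, 0, 2),
                   cost_otc = c(0.98, 0, 3))
  oc <- derive_outcomes(co)
  expect_equal(oc$hba1c_control, c(1L, 0L, 0L))   # strictly below 6.5
  expect_equal(oc$hypo_incidence, c(2L, 0L, 3L))
  expect_equal(oc$cost_total, c(8.33, 0, 6))
  expect_equal(oc$cost_total,
               oc$cost_inpatient + oc$cost_outpatient + oc$cost_otc)
})

test_that("cohort CSV round trip preserves the data", {
  co <- generate_cohort(sim_config(n_patients = 60, seed = 5))
  b <- withr::local_tempfile(fileext = ".csv")
  f <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, b, f)
  back <- read_cohort(b, f)
  expect_equal(nrow(back), 60)
  co_sorted <- co[order(co$patient_id), names(back)]
  back_sorted <- back[order(back$patient_id), ]
  for (a in c("sim_config", "true_arm", "true_propensity")) {
    attr(co_sorted, a) <- NULL
  }
  expect_equal(as.data.frame(back_sorted), as.data.frame(co_sorted),
               tolerance = 1e-12)
})
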