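# Minimal complete cohort scaffold for toy fixtures.
toy_cohort <- function(n, masked, surgery = 0, age = 50, bmi = 25,
                       pmd = 30) {
  tibble::tibble(
    patient_id = seq_len(n), age = age, bmi = bmi, surgery = surgery,
    meno_hrt = factor(rep("premenopausal", n),
                      levels = c("premenopausal", "postmeno_no_hrt",
                                 "postmeno_hrt")),
    technique = factor(rep("analog", n), levels = c("analog", "digital")),
    pmd_observed = pmd, masked = masked
  )
}

test_that("a 2x2 table recovers the closed-form log odds ratio", {
  # exposure (surgery) 0: 10 events / 40 nonevents; 1: 40 / 10
  cohort <- toy_cohort(
    100,
    masked = c(rep(1, 10), rep(0, 40), rep(1, 40), rep(0, 10)),
    surgery = c(rep(0, 50), rep(1, 50))
  )
  fit <- fit_masking_model(cohort, pmd_column = NULL)
  expect_equal(unname(fit$coefficients[["surgery"]]), log(16),
               tolerance = 1e-6)
  expect_equal(unname(fit$coefficients[["intercept"]]), log(10 / 40),
               tolerance = 1e-6)
})

test_that("fitted probabilities average to the observed prevalence", {
  co <- generate_cohort(cohort_params(n = 2000), seed = 5)
  fit <- fit_masking_model(co, "pmd_observed")
  risks <- predict_masking_risk(fit, co)
  expect_equal(mean(risks), mean(co$masked), tolerance = 1e-6)
})

test_that("simulation followed by refitting recovers the truth coefficient-wise", {
  truth <- default_masking_coefficients()$coefficients
  n_rep <- 100
  hits <- matrix(FALSE, n_rep, length(truth))
  for (r in seq_len(n_rep)) {
    co <- generate_cohort(cohort_params(n = 10000), seed = 5000 + r)
    fit <- fit_masking_model(co, "pmd_observed")
    hits[r, ] <- abs(fit$coefficients - truth) < 3 * fit$se
  }
  # nominal 3-SE coverage: expect at least 95 of 100 per coefficient
  expect_true(all(colSums(hits) >= 95))
})

test_that("a null generative model produces null refits", {
  co0 <- masking_risk_coefficients(0, 0, 0, 0, 0, 0, 0, 0)
  co <- generate_cohort(cohort_params(n = 50000), co0, seed = 9)
  fit <- fit_masking_model(co, "pmd_observed")
  within3 <- abs(fit$coefficients) < 3 * fit$se
  expect_gte(sum(within3), 7)
})

test_that("risk prediction follows the logistic formula", {
  co <- default_masking_coefficients()
  patient <- toy_cohort(1, masked = 0)
  # z = -0.906 - 0.018*50 - 0.080*25 + 0.032*40 = -2.526
  risk <- predict_masking_risk(co, patient, pmd_value = 40)
  expect_equal(risk, exp(-2.526) / (1 + exp(-2.526)), tolerance = 1e-9)
  expect_equal(round(risk, 3), 0.074)
  # z = 0 gives risk 1/2
  co0 <- masking_risk_coefficients(0, 0, 0, 0, 0, 0, 0, 0)
  expect_equal(predict_masking_risk(co0, patient, pmd_value = 40), 0.5)
  # risk is strictly increasing in PMD when the PMD slope is positive
  risks <- vapply(seq(0, 100, by = 10), function(p) {
    predict_masking_risk(co, patient, pmd_value = p)
  }, numeric(1))
  expect_true(all(diff(risks) > 0))
})

test_that("degenerate cohorts and unknown levels are rejected", {
  single <- toy_cohort(20, masked = rep(0, 20))
  expect_error(fit_masking_model(single), "Both outcome classes")
  co <- generate_cohort(cohort_params(n = 100), seed = 2)
  bad <- co
  levels(bad$meno_hrt) <- c(levels(bad$meno_hrt), "other")
  bad$meno_hrt[1] <- "other"
  expect_error(
    predict_masking_risk(default_masking_coefficients(), bad),
    "Unknown")
  co_na <- co; co_na$bmi[3] <- NA
  expect_error(fit_masking_model(co_na), "missing")
})

test_that("tidy and glance report the fitted terms", {
  co <- generate_cohort(cohort_params(n = 1000), seed = 11)
  fit <- fit_masking_model(co, "pmd_observed")
  td <- tidy(fit)
  expect_setequal(td$term, c("intercept", "age", "bmi", "surgery",
                             "postmeno_no_hrt", "postmeno_hrt", "digital",
                             "pmd"))
  expect_true(all(td$std.error > 0))
  gl <- glance(fit)
  expect_equal(gl$n, 1000)
  expect_equal(gl$prevalence, mean(co$masked))
})
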