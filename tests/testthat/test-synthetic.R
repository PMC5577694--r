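test_that("generated images hit the target density across the whole range", {
  for (target in seq(0, 100, by = 10)) {
    img <- generate_mammogram(64, 64, target, texture_scale = 4,
                              seed = 11 + target)
    expect_lt(abs(threshold_pmd(img, 128) - target), 1)
  }
  # boundary cases are exact
  expect_equal(threshold_pmd(generate_mammogram(64, 64, 0, 4, 7), 128), 0)
  expect_equal(threshold_pmd(generate_mammogram(64, 64, 100, 4, 7), 128), 100)
  # typical density of a non-masked group, at full working resolution
  img <- generate_mammogram(256, 256, 34.5, 8, 1)
  expect_true(threshold_pmd(img, 128) >= 33.5 &&
                threshold_pmd(img, 128) <= 35.5)
})

test_that("image generation is deterministic per seed and varies across seeds", {
  a <- generate_mammogram(48, 48, 40, seed = 9)
  b <- generate_mammogram(48, 48, 40, seed = 9)
  c <- generate_mammogram(48, 48, 40, seed = 10)
  expect_identical(a$pixels, b$pixels)
  expect_false(identical(a$pixels, c$pixels))
})

test_that("the breast mask is a left-anchored half-ellipse with empty background", {
  img <- generate_mammogram(64, 96, 50, seed = 2)
  expect_true(mean(img$mask) > 0.5 && mean(img$mask) < 0.7)
  expect_true(all(img$pixels[!img$mask] == 0L))
  # attached to the left edge, detached from the right
  expect_true(any(img$mask[, 1]))
  expect_false(any(img$mask[, ncol(img$mask)]))
})

test_that("generate_mammogram rejects invalid inputs", {
  expect_error(generate_mammogram(64, 64, -1), "0, 100")
  expect_error(generate_mammogram(64, 64, 101), "0, 100")
  expect_error(generate_mammogram(16, 64, 50), "small")
})

test_that("cohort_params validates probabilities and spreads", {
  expect_error(cohort_params(p_surgery = 1.2), "0, 1")
  expect_error(cohort_params(p_premeno = 0.5, p_postmeno_nohrt = 0.4,
                             p_postmeno_hrt = 0.2), "sum to 1")
  expect_error(cohort_params(age_sd = 0), "positive")
})

test_that("zero-size cohorts are empty but well formed", {
  co <- generate_cohort(cohort_params(n = 0), seed = 1)
  expect_equal(nrow(co), 0)
  expect_named(co, c("patient_id", "age", "bmi", "surgery", "meno_hrt",
                     "technique", "pmd_observed", "masked"))
})

test_that("a predictor-free generative model yields 50% masking prevalence", {
  co0 <- masking_risk_coefficients(0, 0, 0, 0, 0, 0, 0, 0)
  co <- generate_cohort(cohort_params(n = 10000), co0, seed = 4)
  expect_lt(abs(mean(co$masked) - 0.5), 0.015)
})

test_that("cohort covariates match their generative distributions", {
  p <- cohort_params(n = 100000)
  co <- generate_cohort(p, seed = 8)
  n <- nrow(co)
  expect_true(all(co$pmd_observed >= 0 & co$pmd_observed <= 100))
  expect_true(all(co$masked %in% 0:1))
  expect_false(anyNA(co))
  # age/BMI: truncation at 0 is negligible at these means
  expect_lt(abs(mean(co$age) - p$age_mean), 3 * p$age_sd / sqrt(n))
  expect_lt(abs(mean(co$bmi) - p$bmi_mean), 3 * p$bmi_sd / sqrt(n))
  expect_lt(abs(sd(co$age) - p$age_sd), 3 * p$age_sd / sqrt(2 * n))
  # PMD is sampled from a normal truncated to [0, 100]: compare against
  # the analytic truncated-normal mean/sd (independent closed form)
  a <- (0 - p$pmd_mean) / p$pmd_sd
  b <- (100 - p$pmd_mean) / p$pmd_sd
  zden <- pnorm(b) - pnorm(a)
  tmean <- p$pmd_mean + p$pmd_sd * (dnorm(a) - dnorm(b)) / zden
  tvar <- p$pmd_sd^2 *
    (1 + (a * dnorm(a) - b * dnorm(b)) / zden -
       ((dnorm(a) - dnorm(b)) / zden)^2)
  expect_lt(abs(mean(co$pmd_observed) - tmean), 3 * sqrt(tvar / n))
  expect_lt(abs(sd(co$pmd_observed) - sqrt(tvar)), 3 * sqrt(tvar / (2 * n)))
  # categorical mixes (binomial 3-SE bands)
  for (pr in list(c(mean(co$surgery), p$p_surgery),
                  c(mean(co$technique == "digital"), p$p_digital),
                  c(mean(co$meno_hrt == "premenopausal"), p$p_premeno),
                  c(mean(co$meno_hrt == "postmeno_no_hrt"),
                    p$p_postmeno_nohrt))) {
    expect_lt(abs(pr[1] - pr[2]), 3 * sqrt(pr[2] * (1 - pr[2]) / n))
  }
})

test_that("cohort generation is reproducible per seed", {
  a <- generate_cohort(cohort_params(n = 200), seed = 3)
  b <- generate_cohort(cohort_params(n = 200), seed = 3)
  c <- generate_cohort(cohort_params(n = 200), seed = 4)
  expect_identical(a, b)
  expect_false(identical(a$pmd_observed, c$pmd_observed))
})

test_that("simulated studies bundle cohort and matching feature table", {
  study <- simulate_masking_study(n = 6, seed = 2, image_size = 48)
  expect_equal(nrow(study$cohort), 6)
  expect_equal(dim(study$features), c(6, 364))
  expect_identical(study$features$patient_id, study$cohort$patient_id)
})
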