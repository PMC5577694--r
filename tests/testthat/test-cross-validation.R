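# Small synthetic study shared by the harness tests: masking driven by
# observed PMD, five noisy proxies of PMD as "features".
small_study <- function(n = 240, seed = 1) {
  cohort <- generate_cohort(cohort_params(n = n), seed = seed)
  feats <- withr::with_seed(seed + 100, {
    tibble::tibble(
      patient_id = cohort$patient_id,
      f1 = cohort$pmd_observed + rnorm(n, sd = 5),
      f2 = cohort$pmd_observed + rnorm(n, sd = 10),
      f3 = rnorm(n), f4 = rnorm(n), f5 = rnorm(n)
    )
  })
  list(cohort = cohort, features = feats)
}

test_that("outer folds partition patients and keep both classes in training", {
  co <- generate_cohort(cohort_params(n = 100), seed = 2)
  id <- mammotex:::outer_fold_assignment(co$masked, 3, seed = 7)
  expect_length(id, 100)
  expect_setequal(unique(id), 1:3)
  for (f in 1:3) {
    expect_equal(length(unique(co$masked[id != f])), 2)
  }
  # stratification: event counts differ by at most one across folds
  ev <- table(id[co$masked == 1])
  expect_lte(max(ev) - min(ev), 1)
})

test_that("the report has one record per repetition, fold and model", {
  st <- small_study()
  cfg <- cv_config(n_repetitions = 4, methods = character(0), seed = 3)
  cv <- repeated_double_cv(st$cohort, NULL, cfg)
  expect_equal(nrow(cv$records), 4 * 3 * 3) # null, clinical, observed
  counts <- table(cv$records$model)
  expect_true(all(counts[c("null", "clinical", "observed")] == 12))
})

test_that("the null model scores AUC exactly one half in every fold", {
  st <- small_study()
  cv <- repeated_double_cv(st$cohort, NULL,
                           cv_config(n_repetitions = 3,
                                     methods = character(0), seed = 4))
  null_auc <- cv$records$auc[cv$records$model == "null"]
  expect_true(all(null_auc == 0.5))
  smry <- glance(cv)
  expect_equal(smry$auc_mean[smry$model == "null"], 0.5)
  expect_equal(smry$auc_sd[smry$model == "null"], 0)
})

test_that("validation data never influence the fitted models", {
  st <- small_study()
  cfg <- cv_config(n_repetitions = 1, methods = "lasso", seed = 5,
                   inner_folds = 5)
  train <- st$cohort[1:160, ]
  val <- st$cohort[161:240, ]
  ftr <- st$features[1:160, ]
  fval <- st$features[161:240, ]
  res1 <- mammotex:::evaluate_split(train, val, ftr, fval, cfg, seed = 9)
  val2 <- val
  val2$masked <- 1 - val2$masked # corrupt the held-out outcomes
  val2$pmd_observed <- rev(val2$pmd_observed)
  res2 <- mammotex:::evaluate_split(train, val2, ftr, fval, cfg, seed = 9)
  expect_identical(res1$models, res2$models)
})

test_that("reports aggregate by plain averaging and obey the NRI identity", {
  st <- small_study()
  cfg <- cv_config(n_repetitions = 2, methods = "lasso", seed = 6,
                   inner_folds = 5)
  cv <- repeated_double_cv(st$cohort, st$features, cfg)
  rec <- cv$records
  # independent re-aggregation
  for (m in unique(rec$model)) {
    expect_equal(cv$summary$mse_mean[cv$summary$model == m],
                 mean(rec$mse[rec$model == m]))
    expect_equal(cv$summary$auc_sd[cv$summary$model == m],
                 sd(rec$auc[rec$model == m]))
  }
  # continuous risks are tie-free: the reclassification identity holds
  pm <- rec[!rec$model %in% c("null", "clinical"), ]
  expect_equal(pm$nri,
               (2 * pm$up_events - 1) + (2 * pm$down_nonevents - 1),
               tolerance = 1e-12)
  # discovery table covers every cutoff for every record
  expect_equal(nrow(cv$discovery),
               2 * 3 * 4 * length(cfg$cutoffs)) # reps x folds x models
})

test_that("identical configurations reproduce identical reports", {
  st <- small_study()
  cfg <- cv_config(n_repetitions = 1, methods = "lasso", seed = 8,
                   inner_folds = 5)
  cv1 <- repeated_double_cv(st$cohort, st$features, cfg)
  cv2 <- repeated_double_cv(st$cohort, st$features, cfg)
  expect_identical(cv1$records, cv2$records)
  cv3 <- repeated_double_cv(st$cohort, st$features,
                            cv_config(n_repetitions = 1, methods = "lasso",
                                      seed = 9, inner_folds = 5))
  expect_false(identical(cv1$records$mse, cv3$records$mse))
})

test_that("configuration and input validation catch misuse", {
  expect_error(cv_config(outer_folds = 1), ">= 2")
  expect_error(cv_config(cutoffs = c(0, 50)), "0, 100")
  st <- small_study(n = 60)
  expect_error(
    repeated_double_cv(st$cohort, NULL,
                       cv_config(n_repetitions = 1, methods = "lasso")),
    "features")
  scrambled <- st$features[rev(seq_len(nrow(st$features))), ]
  expect_error(
    repeated_double_cv(st$cohort, scrambled,
                       cv_config(n_repetitions = 1, methods = "lasso")),
    "patient_id")
})

test_that("plot methods return ggplot objects", {
  st <- small_study()
  cv <- repeated_double_cv(st$cohort, NULL,
                           cv_config(n_repetitions = 1,
                                     methods = character(0), seed = 2))
  expect_s3_class(autoplot(cv), "ggplot")
  fit <- fit_masking_model(st$cohort, "pmd_observed")
  risks <- list(observed = predict_masking_risk(fit, st$cohort))
  expect_s3_class(plot_roc_curves(st$cohort, risks), "ggplot")
})
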