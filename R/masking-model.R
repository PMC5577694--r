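#' Coefficients of the logistic masking-risk model
#'
#' The masking-risk model is a logistic regression for mammography failure
#' (a tumor visible on ultrasound but unsuspicious on the mammogram) with
#' the clinical predictors age, BMI, previous breast surgery,
#' menopausal/HRT status and imaging technique, plus one percentage
#' mammographic density term (observed or texture-predicted PMD). The
#' linear predictor is
#' `z = b0 + b_age*age + b_bmi*bmi + b_surgery*surgery +
#'  b_postmeno_no_hrt + b_postmeno_hrt + b_digital + b_pmd*pmd`,
#' with premenopausal, no surgery and analog technique as reference
#' categories (coefficient 0), and the predicted risk is
#' `exp(z) / (1 + exp(z))`.
#'
#' @param intercept Intercept (log-odds).
#' @param age Log-odds per year of age.
#' @param bmi Log-odds per kg/m^2.
#' @param surgery Effect of previous breast surgery (yes vs no).
#' @param postmeno_no_hrt,postmeno_hrt Effects of postmenopausal status
#'   without/with HRT, versus premenopausal.
#' @param digital Effect of digital vs analog imaging.
#' @param pmd Log-odds per percentage point of mammographic density.
#' @param se Optional named vector of standard errors (same names).
#'
#' @return An object of class `masking_coefficients`.
#' @seealso [default_masking_coefficients()], [fit_masking_model()]
#' @examples
#' co <- masking_risk_coefficients(-1, 0, 0, 0, 0, 0, 0, 0.05)
#' co$coefficients["pmd"]
#' @export
masking_risk_coefficients <- function(intercept, age, bmi, surgery,
                                      postmeno_no_hrt, postmeno_hrt,
                                      digital, pmd, se = NULL) {
  beta <- c(intercept = intercept, age = age, bmi = bmi, surgery = surgery,
            postmeno_no_hrt = postmeno_no_hrt, postmeno_hrt = postmeno_hrt,
            digital = digital, pmd = pmd)
  if (anyNA(beta) || any(!is.finite(beta))) {
    abort("All masking-risk coefficients must be finite.")
  }
  if (!is.null(se)) se <- se[names(beta)]
  structure(list(coefficients = beta, se = se),
            class = "masking_coefficients")
}

#' Reference masking-risk coefficients for the synthetic cohort generator
#'
#' A fixed coefficient set on the log-odds scale representing a clinical
#' masking-risk model for a hospital-based diagnostic mammography
#' population, used as the default generative model for synthetic cohorts:
#' masking risk decreases with age and BMI and increases with previous
#' surgery, digital technique and mammographic density (0.032 log-odds per
#' PMD percentage point).
#'
#' @return A [masking_risk_coefficients()] object with standard errors.
#' @examples
#' default_masking_coefficients()$coefficients
#' @export
default_masking_coefficients <- function() {
  masking_risk_coefficients(
    intercept = -0.906, age = -0.018, bmi = -0.080, surgery = 0.502,
    postmeno_no_hrt = -0.530, postmeno_hrt = 0.208, digital = 0.416,
    pmd = 0.032,
    se = c(intercept = 1.308, age = 0.014, bmi = 0.033, surgery = 0.286,
           postmeno_no_hrt = 0.357, postmeno_hrt = 0.355, digital = 0.223,
           pmd = 0.009)
  )
}

as_masking_coefficients <- function(x) {
  if (inherits(x, "masking_coefficients")) return(x)
  if (inherits(x, "masking_model")) {
    return(structure(list(coefficients = x$coefficients, se = x$se),
                     class = "masking_coefficients"))
  }
  abort("Expected `masking_coefficients` or a fitted `masking_model`.")
}

# Linear predictor z of the masking model on a cohort tibble. A NA-free,
# known-level cohort is required; `pmd_column` of NULL drops the PMD term
# (clinical-only model).
masking_linear_predictor <- function(coefs, data, pmd_column = "pmd_observed") {
  beta <- coefs$coefficients
  need <- c("age", "bmi", "surgery", "meno_hrt", "technique")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("Cohort is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  meno <- as.character(data$meno_hrt)
  tech <- as.character(data$technique)
  ok_meno <- c("premenopausal", "postmeno_no_hrt", "postmeno_hrt")
  if (length(meno) > 0 && !all(meno %in% ok_meno)) {
    abort("Unknown `meno_hrt` level in cohort.")
  }
  if (length(tech) > 0 && !all(tech %in% c("analog", "digital"))) {
    abort("Unknown `technique` level in cohort.")
  }
  z <- beta[["intercept"]] +
    beta[["age"]] * data$age +
    beta[["bmi"]] * data$bmi +
    beta[["surgery"]] * data$surgery +
    beta[["postmeno_no_hrt"]] * (meno == "postmeno_no_hrt") +
    beta[["postmeno_hrt"]] * (meno == "postmeno_hrt") +
    beta[["digital"]] * (tech == "digital")
  if (!is.null(pmd_column)) {
    if (!pmd_column %in% names(data)) {
      abort(sprintf("PMD column `%s` not found in cohort.", pmd_column))
    }
    z <- z + beta[["pmd"]] * data[[pmd_column]]
  }
  as.numeric(z)
}

#' Fit the logistic masking-risk model by maximum likelihood
#'
#' Fits masking status on the clinical predictors (age, BMI, previous
#' surgery, menopausal/HRT status, imaging technique) plus one PMD column,
#' by maximum-likelihood logistic regression (iteratively reweighted least
#' squares). Standard errors come from the observed information matrix.
#'
#' @param cohort Cohort tibble as produced by [generate_cohort()]: must
#'   contain `masked` with both outcome classes and no missing values.
#' @param pmd_column Name of the PMD column to include (e.g.
#'   `"pmd_observed"` or a predicted-PMD column), or `NULL` for the
#'   clinical-only model.
#' @param clinical If `FALSE`, drop the clinical predictors too; with
#'   `pmd_column = NULL` this is the predictor-free null model.
#'
#' @return An object of class `masking_model`: coefficients on the
#'   canonical scale of [masking_risk_coefficients()] (absent terms 0 for
#'   reduced models), standard errors, the model formula and fit summaries.
#'   Supports [tidy()], [glance()] and [predict_masking_risk()].
#' @examples
#' cohort <- generate_cohort(cohort_params(n = 500), seed = 1)
#' fit <- fit_masking_model(cohort, "pmd_observed")
#' tidy(fit)
#' @export
fit_masking_model <- function(cohort, pmd_column = "pmd_observed",
                              clinical = TRUE) {
  if (!is.data.frame(cohort) || !"masked" %in% names(cohort)) {
    abort("`cohort` must be a data frame with a `masked` column.")
  }
  if (anyNA(cohort)) abort("Cohort contains missing values.")
  y <- cohort$masked
  if (!all(y %in% c(0, 1))) abort("`masked` must be binary 0/1.")
  if (length(unique(y)) < 2) {
    abort("Both outcome classes must be present to fit the masking model.")
  }
  terms <- character(0)
  if (clinical) {
    # Degenerate covariates (single observed factor level, constant
    # numeric) carry no information and are dropped from the fit; their
    # canonical coefficients stay 0.
    informative <- function(v) {
      if (is.factor(v) || is.character(v)) length(unique(as.character(v))) >= 2
      else sd(v) > 0
    }
    clin <- c("age", "bmi", "surgery", "meno_hrt", "technique")
    terms <- clin[vapply(cohort[clin], informative, logical(1))]
  }
  if (!is.null(pmd_column)) {
    if (!pmd_column %in% names(cohort)) {
      abort(sprintf("PMD column `%s` not found in cohort.", pmd_column))
    }
    terms <- c(terms, pmd_column)
  }
  rhs <- if (length(terms) == 0) "1" else paste(terms, collapse = " + ")
  fml <- stats::as.formula(paste("masked ~", rhs))
  cohort <- droplevels(as.data.frame(cohort))
  fit <- withCallingHandlers(
    glm(fml, family = binomial(), data = cohort,
        control = list(epsilon = 1e-10, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  if (!fit$converged) {
    abort("Logistic fit did not converge (possible complete separation).")
  }
  cf <- coef(fit)
  if (anyNA(cf)) {
    warn("Inestimable (aliased) term(s) set to 0 in the masking model.")
    cf[is.na(cf)] <- 0
  }
  if (any(abs(cf) > 50)) {
    abort("Diverging coefficients: the data appear completely separated.")
  }
  se_raw <- sqrt(diag(vcov(fit)))
  map <- c("(Intercept)" = "intercept", age = "age", bmi = "bmi",
           surgery = "surgery",
           meno_hrtpostmeno_no_hrt = "postmeno_no_hrt",
           meno_hrtpostmeno_hrt = "postmeno_hrt",
           techniquedigital = "digital")
  if (!is.null(pmd_column)) map[pmd_column] <- "pmd"
  beta <- se <- setNames(numeric(8), c("intercept", "age", "bmi", "surgery",
                                       "postmeno_no_hrt", "postmeno_hrt",
                                       "digital", "pmd"))
  fitted_terms <- character(0)
  for (nm in names(cf)) {
    canon <- map[[nm]]
    if (is.null(canon)) canon <- nm
    beta[canon] <- cf[[nm]]
    se[canon] <- if (nm %in% names(se_raw)) se_raw[[nm]] else NA_real_
    fitted_terms <- c(fitted_terms, canon)
  }
  structure(list(
    coefficients = beta, se = se, fitted_terms = fitted_terms,
    pmd_column = pmd_column, clinical = clinical, formula = fml,
    n = nrow(cohort), n_events = sum(y),
    deviance = fit$deviance, null_deviance = fit$null.deviance,
    aic = fit$aic
  ), class = "masking_model")
}

#' Predicted masking risk
#'
#' Evaluates the fitted (or reference) logistic masking model on new
#' patients: covariates and PMD are combined linearly into `z` and the
#' risk is `exp(z) / (1 + exp(z))`.
#'
#' @param model A `masking_model` or [masking_risk_coefficients()] object.
#' @param cohort Cohort tibble (one or more rows) with the clinical
#'   covariate columns.
#' @param pmd_column PMD column to use; defaults to the column the model
#'   was fitted with (for reference coefficient sets, `"pmd_observed"`).
#' @param pmd_value Optional numeric override: use this PMD value (scalar
#'   or per-row vector) instead of a column.
#'
#' @return Numeric vector of masking probabilities in `(0, 1)`.
#' @examples
#' co <- default_masking_coefficients()
#' patient <- tibble::tibble(
#'   age = 50, bmi = 25, surgery = 0,
#'   meno_hrt = factor("premenopausal",
#'     levels = c("premenopausal", "postmeno_no_hrt", "postmeno_hrt")),
#'   technique = factor("analog", levels = c("analog", "digital"))
#' )
#' predict_masking_risk(co, patient, pmd_value = 40)
#' @export
predict_masking_risk <- function(model, cohort, pmd_column = NULL,
                                 pmd_value = NULL) {
  coefs <- as_masking_coefficients(model)
  clinical <- if (inherits(model, "masking_model")) model$clinical else TRUE
  if (!clinical) {
    # null model: intercept only
    return(rep(plogis(coefs$coefficients[["intercept"]]), nrow(cohort)))
  }
  if (!is.null(pmd_value)) {
    tmp <- cohort
    tmp[[".pmd_override"]] <- pmd_value
    z <- masking_linear_predictor(coefs, tmp, ".pmd_override")
  } else {
    if (is.null(pmd_column)) {
      pmd_column <- if (inherits(model, "masking_model")) model$pmd_column
                    else "pmd_observed"
    }
    z <- masking_linear_predictor(coefs, cohort, pmd_column)
  }
  plogis(z)
}

#' @export
print.masking_model <- function(x, ...) {
  cat(sprintf("<masking_model> n = %d (%d events), terms: %s\n",
              x$n, x$n_events, paste(x$fitted_terms, collapse = ", ")))
  print(round(x$coefficients[x$fitted_terms], 4))
  invisible(x)
}

#' Tidy a fitted masking model
#'
#' @param x A `masking_model`.
#' @param ... Unused.
#' @return A tibble with one row per fitted term: `term`, `estimate`,
#'   `std.error`, `statistic` (Wald z) and `p.value`.
#' @export
tidy.masking_model <- function(x, ...) {
  terms <- x$fitted_terms
  est <- x$coefficients[terms]
  se <- x$se[terms]
  stat <- est / se
  tibble::tibble(
    term = terms, estimate = unname(est), std.error = unname(se),
    statistic = unname(stat),
    p.value = 2 * stats::pnorm(-abs(unname(stat)))
  )
}

#' Glance at a fitted masking model
#'
#' @param x A `masking_model`.
#' @param ... Unused.
#' @return One-row tibble: sample size, number of events, deviances and AIC.
#' @export
glance.masking_model <- function(x, ...) {
  tibble::tibble(
    n = x$n, n_events = x$n_events, prevalence = x$n_events / x$n,
    deviance = x$deviance, null_deviance = x$null_deviance, aic = x$aic
  )
}
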