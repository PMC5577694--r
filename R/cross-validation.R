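# ---- Repeated double (nested) cross-validation ---------------------------

#' Configuration of the repeated double cross-validation
#'
#' The outer loop splits the cohort into `outer_folds` parts
#' (stratified by masking status so that rare events reach every fold),
#' fits everything on the training two-thirds and evaluates on the
#' held-out third; the inner loop (10-fold by default, out-of-bag error
#' for the forest) chooses each method's tuning parameter using training
#' data only. The whole procedure is repeated `n_repetitions` times with
#' fresh fold assignments, giving `n_repetitions * outer_folds` records
#' per model.
#'
#' @param n_repetitions Number of repetitions (the study design uses 100).
#' @param outer_folds Number of outer folds (study design: 3).
#' @param inner_folds Number of inner tuning folds (study design: 10).
#' @param seed Integer seed; every fold assignment and forest fit derives
#'   its own stream from it.
#' @param methods Subset of `c("univariate", "lasso", "boosting",
#'   "forest")` to run as predicted-PMD models; may be empty to evaluate
#'   only the null, clinical-only and observed-PMD models.
#' @param cutoffs Risk cut-off points in percent for [discovery_rates()].
#' @param grids Optional named list of tuning grids per method.
#' @param boost_step Boosting step size.
#' @param stratify Stratify outer folds by masking status (default TRUE).
#'
#' @return A list of class `cv_config`.
#' @export
cv_config <- function(n_repetitions = 100, outer_folds = 3,
                      inner_folds = 10, seed = 1,
                      methods = c("univariate", "lasso", "boosting",
                                  "forest"),
                      cutoffs = c(5, 10, 12, 15, 20),
                      grids = list(), boost_step = 0.1, stratify = TRUE) {
  if (outer_folds < 2 || inner_folds < 2) abort("Folds must be >= 2.")
  if (length(cutoffs) > 0 && any(cutoffs <= 0 | cutoffs >= 100)) {
    abort("`cutoffs` must lie in (0, 100).")
  }
  if (length(methods) > 0) {
    methods <- unname(match.arg(methods,
                                c("univariate", "lasso", "boosting",
                                  "forest"),
                                several.ok = TRUE))
  } else {
    methods <- character(0)
  }
  structure(list(
    n_repetitions = as.integer(n_repetitions),
    outer_folds = as.integer(outer_folds),
    inner_folds = as.integer(inner_folds),
    seed = as.integer(seed), methods = methods, cutoffs = cutoffs,
    grids = grids, boost_step = boost_step, stratify = stratify
  ), class = "cv_config")
}

# Outer fold assignment, stratified by outcome, guaranteed to leave both
# classes in every training set (re-randomized otherwise, at most 20
# attempts).
outer_fold_assignment <- function(masked, k, seed, stratify = TRUE) {
  n <- length(masked)
  for (attempt in 1:20) {
    id <- withr::with_seed(derive_seed(seed, attempt), {
      if (stratify) {
        out <- integer(n)
        for (cls in unique(masked)) {
          idx <- which(masked == cls)
          out[idx] <- sample(rep(seq_len(k), length.out = length(idx)))
        }
        out
      } else {
        sample(rep(seq_len(k), length.out = n))
      }
    })
    ok <- all(vapply(seq_len(k), function(f) {
      length(unique(masked[id != f])) == 2
    }, logical(1)))
    if (ok) return(id)
  }
  abort("Could not build outer folds with both classes in every training set.")
}

# Fit all masking models on the training part and evaluate them on the
# validation part of one outer split. Nothing from `val` influences any
# fitting or tuning step.
evaluate_split <- function(train, val, features_train, features_val,
                           config, seed) {
  model_frames_tr <- list(null = NULL, clinical = NULL)
  model_frames_val <- list(null = NULL, clinical = NULL)
  lambdas <- list()

  train_aug <- train
  val_aug <- val
  for (mi in seq_along(config$methods)) {
    m <- config$methods[mi]
    tune <- tune_lambda(
      features_train, train$pmd_observed, method = m,
      grid = config$grids[[m]], folds = config$inner_folds,
      seed = derive_seed(seed, 7, mi), step = config$boost_step
    )
    fit <- fit_pmd_model(features_train, train$pmd_observed, method = m,
                         lambda = tune$best_lambda,
                         seed = derive_seed(seed, 8, mi),
                         step = config$boost_step)
    colname <- paste0("pmd_pred_", m)
    train_aug[[colname]] <- predict_pmd(fit, features_train)
    val_aug[[colname]] <- predict_pmd(fit, features_val)
    lambdas[[m]] <- tune$best_lambda
  }

  specs <- c(
    list(null = list(pmd = NULL, clinical = FALSE),
         clinical = list(pmd = NULL, clinical = TRUE)),
    setNames(lapply(config$methods, function(m) {
      list(pmd = paste0("pmd_pred_", m), clinical = TRUE)
    }), config$methods),
    list(observed = list(pmd = "pmd_observed", clinical = TRUE))
  )

  fits <- lapply(specs, function(sp) {
    fit_masking_model(train_aug, pmd_column = sp$pmd, clinical = sp$clinical)
  })
  risks <- lapply(fits, function(f) predict_masking_risk(f, val_aug))
  risk_clinical <- risks$clinical

  records <- purrr::imap_dfr(risks, function(risk, model) {
    rec <- tibble::tibble(
      model = model,
      mse = brier_mse(val$masked, risk),
      auc = auc(val$masked, risk),
      nri = NA_real_, up_events = NA_real_, down_nonevents = NA_real_,
      lambda = if (model %in% names(lambdas)) lambdas[[model]] else NA_real_
    )
    if (!model %in% c("null", "clinical")) {
      nri <- continuous_nri(val$masked, risk, risk_clinical)
      rec$nri <- nri$nri
      rec$up_events <- nri$up_events
      rec$down_nonevents <- nri$down_nonevents
    }
    rec
  })

  discovery <- purrr::imap_dfr(risks, function(risk, model) {
    dplyr::mutate(discovery_rates(val$masked, risk, config$cutoffs),
                  model = model, .before = 1)
  })

  list(records = records, discovery = discovery,
       models = lapply(fits, function(f) f$coefficients))
}

#' Repeated double cross-validation of the masking models
#'
#' The full evaluation harness: for each repetition and outer fold, the
#' tuning parameter of every requested PMD method is chosen by inner
#' cross-validation on the outer-training data, the PMD model is fitted
#' there, predicted PMD is computed for training and validation parts,
#' all masking logistic models (predictor-free null, clinical-only, one
#' per predicted-PMD method, observed-PMD) are fitted on the training
#' part, and Brier MSE, AUC, continuous NRI versus the clinical model and
#' discovery rates are measured on the held-out part. No validation-fold
#' datum influences any fitting or tuning step.
#'
#' @param cohort Cohort tibble (see [generate_cohort()]); keyed by
#'   `patient_id` when features are supplied.
#' @param features Feature table with `patient_id` matching the cohort,
#'   or `NULL` when `config$methods` is empty.
#' @param config A [cv_config()].
#'
#' @return An object of class `masking_cv`: list with `records` (one row
#'   per repetition x fold x model), `discovery` (per-record discovery
#'   rates), `summary` and `discovery_summary` (means and SDs over all
#'   records) and the `config`. Supports [tidy()], [glance()] and
#'   [autoplot()].
#' @examples
#' cohort <- generate_cohort(cohort_params(n = 300), seed = 1)
#' cv <- repeated_double_cv(cohort, NULL,
#'   cv_config(n_repetitions = 2, methods = character(0), seed = 1))
#' glance(cv)
#' @export
repeated_double_cv <- function(cohort, features = NULL,
                               config = cv_config()) {
  if (!inherits(config, "cv_config")) abort("`config` must be a `cv_config`.")
  if (length(config$methods) > 0) {
    if (is.null(features)) {
      abort("`features` is required when PMD methods are requested.")
    }
    if (!identical(features$patient_id, cohort$patient_id)) {
      abort("`features` and `cohort` must share the same `patient_id` order.")
    }
  }
  if (length(unique(cohort$masked)) < 2) {
    abort("Both outcome classes must be present in the cohort.")
  }

  all_records <- list()
  all_discovery <- list()
  idx <- 1L
  for (rep_i in seq_len(config$n_repetitions)) {
    fold_id <- outer_fold_assignment(
      cohort$masked, config$outer_folds,
      seed = derive_seed(config$seed, 11, rep_i),
      stratify = config$stratify
    )
    for (fold in seq_len(config$outer_folds)) {
      tr <- fold_id != fold
      res <- evaluate_split(
        cohort[tr, , drop = FALSE], cohort[!tr, , drop = FALSE],
        if (!is.null(features)) features[tr, , drop = FALSE],
        if (!is.null(features)) features[!tr, , drop = FALSE],
        config, seed = derive_seed(config$seed, 13, rep_i, fold)
      )
      all_records[[idx]] <- dplyr::mutate(res$records,
                                          repetition = rep_i, fold = fold,
                                          .before = 1)
      all_discovery[[idx]] <- dplyr::mutate(res$discovery,
                                            repetition = rep_i, fold = fold,
                                            .before = 1)
      idx <- idx + 1L
    }
  }
  records <- dplyr::bind_rows(all_records)
  discovery <- dplyr::bind_rows(all_discovery)

  model_levels <- c("null", "clinical", config$methods, "observed")
  records$model <- factor(records$model, levels = model_levels)
  discovery$model <- factor(discovery$model, levels = model_levels)

  summary <- records |>
    dplyr::group_by(.data$model) |>
    dplyr::summarise(
      n_records = dplyr::n(),
      mse_mean = mean(.data$mse), mse_sd = sd(.data$mse),
      auc_mean = mean(.data$auc), auc_sd = sd(.data$auc),
      nri_mean = mean(.data$nri), nri_sd = sd(.data$nri),
      up_events_mean = mean(.data$up_events),
      down_nonevents_mean = mean(.data$down_nonevents),
      .groups = "drop"
    )
  discovery_summary <- discovery |>
    dplyr::group_by(.data$model, .data$cutoff) |>
    dplyr::summarise(
      frequency_above = mean(.data$frequency_above),
      discovery_rate = mean(.data$discovery_rate),
      .groups = "drop"
    )

  structure(list(records = records, discovery = discovery,
                 summary = summary, discovery_summary = discovery_summary,
                 config = config),
            class = "masking_cv")
}

#' @export
print.masking_cv <- function(x, ...) {
  cat(sprintf("<masking_cv> %d repetitions x %d outer folds\n",
              x$config$n_repetitions, x$config$outer_folds))
  print(as.data.frame(x$summary), digits = 4)
  invisible(x)
}

#' Tidy a cross-validation report
#'
#' @param x A `masking_cv`.
#' @param ... Unused.
#' @return The per-record tibble: one row per repetition x outer fold x
#'   model with `mse`, `auc`, `nri`, reclassification components and the
#'   selected tuning value.
#' @export
tidy.masking_cv <- function(x, ...) x$records

#' Summarize a cross-validation report
#'
#' @param x A `masking_cv`.
#' @param ... Unused.
#' @return One row per model: mean and SD of MSE, AUC and NRI over all
#'   records (the arithmetic mean over repetitions x folds).
#' @export
glance.masking_cv <- function(x, ...) x$summary

#' Plot cross-validated AUC (or another metric) by model
#'
#' @param object A `masking_cv`.
#' @param metric One of `"auc"`, `"mse"`, `"nri"`.
#' @param ... Unused.
#' @return A ggplot: per-record distribution of the metric by model.
#' @export
autoplot.masking_cv <- function(object, metric = c("auc", "mse", "nri"),
                                ...) {
  metric <- match.arg(metric)
  df <- object$records[!is.na(object$records[[metric]]), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$model, y = .data[[metric]])) +
    ggplot2::geom_boxplot(fill = "grey85") +
    ggplot2::labs(x = NULL, y = toupper(metric),
                  title = "Repeated double cross-validation") +
    ggplot2::theme_minimal()
}

#' Plot cross-validated ROC curves for the masking models
#'
#' Convenience plot: refits each masking model on a single stratified
#' split of the cohort and draws the validation ROC curves.
#'
#' @param cohort Cohort tibble.
#' @param risks Named list of risk vectors (as from
#'   [predict_masking_risk()]) evaluated on `cohort$masked`.
#' @return A ggplot with one ROC curve per model.
#' @export
plot_roc_curves <- function(cohort, risks) {
  df <- purrr::imap_dfr(risks, function(r, nm) {
    dplyr::mutate(roc_points(cohort$masked, r), model = nm)
  })
  ggplot2::ggplot(df, ggplot2::aes(.data$fpr, .data$tpr,
                                   colour = .data$model)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(linetype = 2, colour = "grey") +
    ggplot2::labs(x = "False-positive rate", y = "True-positive rate") +
    ggplot2::theme_minimal()
}
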