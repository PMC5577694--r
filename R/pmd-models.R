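# ---- Percentage-mammographic-density prediction models -------------------
#
# Four selection/regression techniques predict observed PMD from texture
# features: univariate selection (top-k by F-test), lasso, component-wise
# gradient boosting (L2Boost with simple linear base learners, authored
# here) and random forest. Each technique has one tuning parameter lambda:
# the number of top-ranked features, the penalty, the number of boosting
# iterations, or the number of candidate variables per split.

# Drop the id column and return the numeric feature matrix.
feature_matrix <- function(X, features = NULL) {
  df <- as.data.frame(X)
  df <- df[, setdiff(names(df), "patient_id"), drop = FALSE]
  if (!is.null(features)) {
    missing_cols <- setdiff(features, names(df))
    if (length(missing_cols) > 0) {
      abort(paste0("Feature column(s) not found: ",
                   paste(head(missing_cols, 5), collapse = ", ")))
    }
    df <- df[, features, drop = FALSE]
  }
  as.matrix(df)
}

new_pmd_model <- function(method, lambda, intercept, coefficients,
                          forest = NULL, ranking = NULL, oob_mse = NULL) {
  structure(list(method = method, lambda = lambda, intercept = intercept,
                 coefficients = coefficients, forest = forest,
                 ranking = ranking, oob_mse = oob_mse),
            class = "pmd_model")
}

#' Rank features by univariate F tests
#'
#' Each feature is scored by the global F statistic of the simple linear
#' regression of the response on that feature alone (equal to the squared
#' t statistic of the slope), and features are ordered by increasing
#' p value. Constant features get p value 1 and rank last; ties keep the
#' input column order.
#'
#' @param X Feature table (data frame; a `patient_id` column is ignored).
#' @param y Numeric response (observed PMD).
#' @return Character vector of feature names, best first.
#' @examples
#' X <- tibble::tibble(a = rnorm(30), b = rnorm(30))
#' y <- X$b + rnorm(30, sd = 0.1)
#' rank_univariate(X, y)[1]
#' @export
rank_univariate <- function(X, y) {
  x <- feature_matrix(X)
  n <- nrow(x)
  if (n < 3) abort("At least 3 observations are required.")
  if (length(y) != n) abort("`y` must match the number of rows of `X`.")
  sdx <- apply(x, 2, sd)
  r <- suppressWarnings(as.vector(cor(x, y)))
  r[!is.finite(r)] <- 0
  r2 <- pmin(r^2, 1)
  fstat <- ifelse(sdx == 0, 0, (n - 2) * r2 / pmax(1 - r2, .Machine$double.eps))
  pval <- ifelse(sdx == 0, 1, pf(fstat, 1, n - 2, lower.tail = FALSE))
  colnames(x)[order(pval, seq_along(pval))]
}

#' Fit PMD on the top-k univariately ranked features
#'
#' Ordinary least squares on the `k` best features of [rank_univariate()].
#' Collinear columns are dropped with a warning.
#'
#' @inheritParams rank_univariate
#' @param k Number of top-ranked features (the tuning parameter).
#' @param ranking Optional precomputed ranking (to avoid re-ranking).
#' @return A `pmd_model` (method `"univariate"`, `lambda = k`).
#' @export
fit_top_k <- function(X, y, k, ranking = NULL) {
  if (is.null(ranking)) ranking <- rank_univariate(X, y)
  k <- as.integer(k)
  if (k < 1 || k > length(ranking)) abort("`k` out of range.")
  sel <- ranking[seq_len(k)]
  x <- feature_matrix(X, sel)
  fit <- lm(y ~ x)
  cf <- coef(fit)
  names(cf) <- c("(Intercept)", sel)
  if (anyNA(cf)) {
    dropped <- names(cf)[is.na(cf)]
    warn(paste0("Dropping collinear feature(s): ",
                paste(head(dropped, 5), collapse = ", ")))
    cf[is.na(cf)] <- 0
  }
  new_pmd_model("univariate", k, cf[[1]], cf[-1], ranking = ranking)
}

#' Fit a lasso PMD model
#'
#' Minimizes `(1/2n) * RSS + lambda * sum(|beta|)` with an unpenalized
#' intercept; features are standardized internally and coefficients are
#' returned on the original scale. Large enough `lambda` shrinks every
#' coefficient to exactly zero; `lambda = 0` reproduces ordinary least
#' squares.
#'
#' @inheritParams rank_univariate
#' @param lambda Non-negative penalty (the tuning parameter).
#' @return A `pmd_model` (method `"lasso"`).
#' @export
fit_lasso <- function(X, y, lambda) {
  if (lambda < 0) abort("`lambda` must be non-negative.")
  x <- feature_matrix(X)
  n <- nrow(x)
  # Entry value of the penalty (above it every coefficient is zero), on
  # glmnet's internal 1/n-standardized scale.
  sdev <- sqrt(colMeans(x^2) - colMeans(x)^2)
  act <- sdev > 0
  lmax <- if (any(act)) {
    xs <- sweep(sweep(x[, act, drop = FALSE], 2, colMeans(x[, act, drop = FALSE])),
                2, sdev[act], `/`)
    max(abs(crossprod(xs, y - mean(y)))) / n
  } else 0
  if (lmax <= 0 || lambda >= lmax) {
    cf <- setNames(numeric(ncol(x)), colnames(x))
    return(new_pmd_model("lasso", lambda, mean(y), cf))
  }
  # Warm-started path from the entry value down to the requested penalty.
  path <- exp(seq(log(lmax), log(max(lambda, lmax * 1e-4)),
                  length.out = 30))
  path <- sort(unique(c(path, lambda)), decreasing = TRUE)
  xfit <- x
  if (ncol(xfit) == 1L) xfit <- cbind(xfit, .pad = 0) # glmnet needs >= 2 cols
  fit <- glmnet::glmnet(xfit, y, alpha = 1, standardize = TRUE,
                        lambda = path, thresh = 1e-11, maxit = 10^6)
  k <- which.min(abs(fit$lambda - lambda)) # lambda is on the fitted path
  cf <- c(fit$a0[[k]], as.vector(fit$beta[, k]))[seq_len(ncol(x) + 1L)]
  names(cf) <- c("(Intercept)", colnames(x))
  new_pmd_model("lasso", lambda, cf[[1]], cf[-1])
}

#' Component-wise gradient boosting (L2Boost) for PMD
#'
#' Iterative residual fitting with simple linear base learners: starting
#' from the intercept-only model (the mean response), each iteration fits
#' every feature's least-squares slope to the current residuals, selects
#' the feature that most reduces the residual sum of squares, and adds a
#' small multiple (`step`) of that slope to the feature's coefficient.
#' More relevant predictors enter earlier; the iteration count is the
#' tuning parameter controlling both selection and shrinkage. Features are
#' standardized internally; coefficients are returned on the original
#' scale.
#'
#' @inheritParams rank_univariate
#' @param n_iter Number of boosting iterations (>= 0; 0 gives the
#'   intercept-only model).
#' @param step Step size in `(0, 1]`, default 0.1.
#' @return A `pmd_model` (method `"boosting"`, `lambda = n_iter`) whose
#'   `path` attribute records the per-iteration selections.
#' @examples
#' X <- tibble::tibble(a = rnorm(40), b = rnorm(40))
#' y <- 2 * X$a + rnorm(40, sd = 0.1)
#' m <- boost_componentwise(X, y, n_iter = 50)
#' predict_pmd(m, X)[1:3]
#' @export
boost_componentwise <- function(X, y, n_iter, step = 0.1) {
  if (n_iter < 0) abort("`n_iter` must be >= 0.")
  if (!(step > 0 && step <= 1)) abort("`step` must lie in (0, 1].")
  x <- feature_matrix(X)
  n <- nrow(x); p <- ncol(x)
  mu <- colMeans(x)
  sdev <- apply(x, 2, sd)
  active <- sdev > 0
  xs <- sweep(x, 2, mu)
  xs[, active] <- sweep(xs[, active, drop = FALSE], 2, sdev[active], `/`)
  xs[, !active] <- 0
  ssx <- colSums(xs^2)

  beta_std <- numeric(p)
  u <- y - mean(y)
  sel_j <- integer(n_iter); sel_b <- numeric(n_iter)
  iters <- 0L
  if (any(active)) {
    for (it in seq_len(n_iter)) {
      cp <- crossprod(xs, u) # p x 1
      score <- ifelse(ssx > 0, cp^2 / ssx, -Inf)
      j <- which.max(score)
      if (!is.finite(score[j]) || score[j] <= 0) break
      b <- cp[j] / ssx[j]
      beta_std[j] <- beta_std[j] + step * b
      u <- u - step * b * xs[, j]
      iters <- it
      sel_j[it] <- j; sel_b[it] <- step * b
    }
  }
  beta <- numeric(p)
  beta[active] <- beta_std[active] / sdev[active]
  names(beta) <- colnames(x)
  intercept <- mean(y) - sum(beta * mu)
  model <- new_pmd_model("boosting", n_iter, intercept, beta)
  model$path <- list(j = sel_j[seq_len(iters)], b = sel_b[seq_len(iters)],
                     mu = mu, sd = sdev, y_bar = mean(y),
                     features = colnames(x))
  model
}

#' Fit a random-forest PMD model
#'
#' Regression forest with bootstrap resampling; the number of candidate
#' variables per split (`mtry`) is the tuning parameter, chosen by
#' out-of-bag error rather than cross-validation.
#'
#' @inheritParams rank_univariate
#' @param mtry Number of candidate features per split.
#' @param n_trees Number of trees (default 500).
#' @param seed Integer seed; the same seed reproduces the forest.
#' @return A `pmd_model` (method `"forest"`) carrying the fitted forest
#'   and its out-of-bag MSE.
#' @export
fit_forest <- function(X, y, mtry, n_trees = 500, seed = 1) {
  x <- feature_matrix(X)
  if (nrow(x) < 2) abort("At least 2 observations are required.")
  if (mtry < 1 || mtry > ncol(x)) abort("`mtry` out of range.")
  fit <- withr::with_seed(as.integer(seed), {
    randomForest::randomForest(x = x, y = y, mtry = mtry, ntree = n_trees)
  })
  new_pmd_model("forest", mtry, NA_real_, numeric(0), forest = fit,
                oob_mse = unname(fit$mse[n_trees]))
}

# Default tuning grids per method.
default_lambda_grid <- function(method, X, y) {
  x <- feature_matrix(X)
  p <- ncol(x); n <- nrow(x)
  switch(method,
    univariate = seq_len(min(150L, p, n - 2L)),
    lasso = glmnet::glmnet(x, y, alpha = 1, nlambda = 50)$lambda,
    boosting = sort(unique(round(exp(seq(log(1), log(2000),
                                         length.out = 30))))),
    forest = sort(unique(pmax(1L, round(p * c(0.1, 0.2, 1 / 3, 0.5))))),
    abort(sprintf("Unknown method `%s`.", method))
  )
}

#' Select the tuning parameter by inner cross-validation (or OOB error)
#'
#' For univariate selection, lasso and boosting: k-fold cross-validation
#' on the supplied data with a fold assignment fixed by `seed` and shared
#' across the whole grid; the `lambda` with the smallest mean held-out
#' MSE wins, ties going to the smallest value. For the random forest, the
#' `mtry` grid is scored by out-of-bag error instead.
#'
#' @inheritParams rank_univariate
#' @param method One of `"univariate"`, `"lasso"`, `"boosting"`,
#'   `"forest"`.
#' @param grid Candidate tuning values; a method-specific default is used
#'   when `NULL`.
#' @param folds Number of inner folds (default 10; ignored for forest).
#' @param seed Integer seed for fold assignment (and forest fits).
#' @param step Boosting step size.
#' @return A list of class `tuning_result`: `method`, `grid`, `cv_mse`
#'   and `best_lambda`.
#' @examples
#' X <- tibble::tibble(a = rnorm(60), b = rnorm(60))
#' y <- X$a + rnorm(60)
#' tune_lambda(X, y, "lasso", grid = c(0.01, 0.1, 1), folds = 5)$best_lambda
#' @export
tune_lambda <- function(X, y, method, grid = NULL, folds = 10, seed = 1,
                        step = 0.1) {
  method <- match.arg(method, c("univariate", "lasso", "boosting", "forest"))
  if (is.null(grid)) grid <- default_lambda_grid(method, X, y)
  if (length(grid) == 0) abort("`grid` must be non-empty.")
  n <- nrow(X)

  if (method == "forest") {
    oob <- vapply(seq_along(grid), function(i) {
      fit_forest(X, y, mtry = grid[i], seed = derive_seed(seed, i))$oob_mse
    }, numeric(1))
    best <- min(grid[oob == min(oob)])
    return(structure(list(method = method, grid = grid, cv_mse = oob,
                          best_lambda = best), class = "tuning_result"))
  }

  if (folds < 2) abort("`folds` must be >= 2.")
  fold_id <- withr::with_seed(as.integer(seed), {
    sample(rep(seq_len(folds), length.out = n))
  })
  if (min(tabulate(fold_id, folds)) < 1) abort("Empty inner fold.")
  grid <- sort(grid) # ascending; ties in MSE resolve to the smallest value
  err <- matrix(NA_real_, folds, length(grid))
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    Xtr <- X[tr, , drop = FALSE]; ytr <- y[tr]
    Xte <- X[!tr, , drop = FALSE]; yte <- y[!tr]
    pred <- switch(method,
      univariate = {
        ranking <- rank_univariate(Xtr, ytr)
        kmax <- min(length(ranking), nrow(Xtr) - 2L)
        vapply(grid, function(k) {
          if (k > kmax) return(rep(NA_real_, length(yte)))
          m <- suppressWarnings(fit_top_k(Xtr, ytr, k, ranking = ranking))
          predict_pmd(m, Xte)
        }, numeric(length(yte)))
      },
      lasso = {
        xtr <- feature_matrix(Xtr)
        fit <- glmnet::glmnet(xtr, ytr, alpha = 1,
                              lambda = sort(grid, decreasing = TRUE))
        pr <- predict(fit, newx = feature_matrix(Xte), s = grid)
        matrix(pr, ncol = length(grid))
      },
      boosting = boost_path_predictions(Xtr, ytr, Xte, grid, step)
    )
    pred <- matrix(pred, ncol = length(grid))
    err[f, ] <- colMeans((yte - pred)^2)
  }
  cv_mse <- colMeans(err)
  ok <- is.finite(cv_mse)
  best <- min(grid[ok][cv_mse[ok] == min(cv_mse[ok])])
  structure(list(method = method, grid = grid, cv_mse = cv_mse,
                 best_lambda = best), class = "tuning_result")
}

# Run one boosting path on the training part and return held-out
# predictions at each grid iteration (columns = grid values, ascending).
boost_path_predictions <- function(Xtr, ytr, Xte, grid, step = 0.1) {
  grid <- sort(grid)
  m <- boost_componentwise(Xtr, ytr, n_iter = max(grid), step = step)
  path <- m$path
  xte <- feature_matrix(Xte, path$features)
  xte_s <- sweep(xte, 2, path$mu)
  act <- path$sd > 0
  xte_s[, act] <- sweep(xte_s[, act, drop = FALSE], 2, path$sd[act], `/`)
  xte_s[, !act] <- 0
  pred <- rep(path$y_bar, nrow(xte))
  out <- matrix(NA_real_, nrow(xte), length(grid))
  gi <- 1L
  n_steps <- length(path$j)
  for (it in seq_len(max(grid))) {
    if (it <= n_steps) {
      pred <- pred + path$b[it] * xte_s[, path$j[it]]
    }
    while (gi <= length(grid) && grid[gi] == it) {
      out[, gi] <- pred
      gi <- gi + 1L
    }
  }
  while (gi <= length(grid)) { # grid beyond path end (early stop)
    out[, gi] <- pred
    gi <- gi + 1L
  }
  out
}

#' Fit a PMD model by method name at a given tuning value
#'
#' Thin dispatcher used by the cross-validation harness.
#'
#' @inheritParams tune_lambda
#' @param lambda Tuning value (see the individual fitting functions).
#' @return A `pmd_model`.
#' @export
fit_pmd_model <- function(X, y, method, lambda, seed = 1, step = 0.1) {
  method <- match.arg(method, c("univariate", "lasso", "boosting", "forest"))
  switch(method,
    univariate = suppressWarnings(fit_top_k(X, y, lambda)),
    lasso = fit_lasso(X, y, lambda),
    boosting = boost_componentwise(X, y, lambda, step = step),
    forest = fit_forest(X, y, mtry = lambda, seed = seed)
  )
}

#' Predict PMD for new images
#'
#' Linear models return `intercept + sum(beta * x)`; the forest returns
#' the tree average. Predictions are deliberately not clipped to
#' `[0, 100]`: the downstream masking model consumes them linearly.
#'
#' @param model A `pmd_model`.
#' @param X Feature table containing every feature the model references.
#' @return Numeric vector of predicted PMD values.
#' @export
predict_pmd <- function(model, X) {
  if (!inherits(model, "pmd_model")) abort("`model` must be a `pmd_model`.")
  if (model$method == "forest") {
    x <- feature_matrix(X, rownames(model$forest$importance))
    return(as.numeric(predict(model$forest, x)))
  }
  used <- names(model$coefficients)[model$coefficients != 0]
  x <- feature_matrix(X, used)
  as.numeric(model$intercept +
               x %*% model$coefficients[used])
}

#' @export
predict.pmd_model <- function(object, newdata, ...) predict_pmd(object, newdata)

#' @export
print.pmd_model <- function(x, ...) {
  nz <- sum(x$coefficients != 0)
  cat(sprintf("<pmd_model> method = %s, lambda = %s, %d nonzero coefficient(s)\n",
              x$method, format(x$lambda), nz))
  invisible(x)
}

#' Tidy a fitted PMD model
#'
#' @param x A `pmd_model`.
#' @param ... Unused.
#' @return Tibble of nonzero terms (`term`, `estimate`), intercept first.
#'   Forests have no coefficients and return only metadata via
#'   [glance.pmd_model()].
#' @export
tidy.pmd_model <- function(x, ...) {
  if (x$method == "forest") {
    return(tibble::tibble(term = character(), estimate = numeric()))
  }
  nz <- x$coefficients[x$coefficients != 0]
  tibble::tibble(term = c("(Intercept)", names(nz)),
                 estimate = c(x$intercept, unname(nz)))
}

#' Glance at a fitted PMD model
#'
#' @param x A `pmd_model`.
#' @param ... Unused.
#' @return One-row tibble: `method`, `lambda`, `n_selected` (nonzero
#'   coefficients; `NA` for the forest) and `oob_mse` (forest only).
#' @export
glance.pmd_model <- function(x, ...) {
  tibble::tibble(
    method = x$method, lambda = as.numeric(x$lambda),
    n_selected = if (x$method == "forest") NA_integer_
                 else sum(x$coefficients != 0),
    oob_mse = x$oob_mse %||% NA_real_
  )
}
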