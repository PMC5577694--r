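test_that("univariate ranking reproduces closed-form F statistics", {
  withr::with_seed(1, {
    x1 <- rnorm(25); x2 <- rnorm(25)
    y <- 1 + 0.8 * x1 + rnorm(25, sd = 0.5)
  })
  X <- tibble::tibble(a = x1, b = x2)
  # hand OLS per feature: F = t^2 of the slope
  f_hand <- vapply(list(x1, x2), function(x) {
    fit <- summary(lm(y ~ x))
    unname(fit$coefficients[2, "t value"]^2)
  }, numeric(1))
  n <- 25
  r <- c(cor(x1, y), cor(x2, y))
  f_mine <- (n - 2) * r^2 / (1 - r^2)
  expect_equal(f_mine, f_hand, tolerance = 1e-9)
  expect_equal(rank_univariate(X, y), c("a", "b"))
  # a feature identical to y ranks first
  X$c <- y
  expect_equal(rank_univariate(X, y)[1], "c")
  # constant features rank last
  X$flat <- 1
  expect_equal(tail(rank_univariate(X, y), 1), "flat")
})

test_that("null univariate p-values are uniform", {
  withr::with_seed(3, {
    X <- noise_features(1000, 30, seed = 33)
    y <- rnorm(1000)
  })
  n <- 1000
  r <- as.vector(cor(as.matrix(X), y))
  pvals <- pf((n - 2) * r^2 / (1 - r^2), 1, n - 2, lower.tail = FALSE)
  expect_gt(ks.test(pvals, "punif")$p.value, 0.01)
  # and the ranking orders by exactly these p-values
  expect_equal(rank_univariate(X, y), names(X)[order(pvals)])
})

test_that("top-k regression equals OLS and nests properly", {
  prob <- linear_pmd_problem(100, p = 8, r2 = 0.9, seed = 2)
  m_all <- fit_top_k(prob$X, prob$y, k = 8)
  ols <- coef(lm(prob$y ~ as.matrix(prob$X)))
  expect_equal(unname(c(m_all$intercept,
                        m_all$coefficients[names(prob$X)])),
               unname(ols), tolerance = 1e-9)
  # noiseless single feature
  y1 <- 2 * prob$X$f03
  m1 <- fit_top_k(prob$X, y1, k = 1)
  expect_equal(unname(m1$coefficients[["f03"]]), 2, tolerance = 1e-9)
  expect_equal(m1$intercept, 0, tolerance = 1e-9)
  # training MSE is non-increasing in k
  mse_k <- vapply(c(1, 3, 5, 8), function(k) {
    m <- fit_top_k(prob$X, prob$y, k)
    mean((prob$y - predict_pmd(m, prob$X))^2)
  }, numeric(1))
  expect_true(all(diff(mse_k) <= 1e-12))
})

test_that("lasso matches its closed-form oracles", {
  prob <- linear_pmd_problem(80, p = 6, r2 = 0.8, seed = 4)
  # unpenalized limit equals OLS
  m0 <- fit_lasso(prob$X, prob$y, 0)
  ols <- coef(lm(prob$y ~ as.matrix(prob$X)))
  expect_equal(unname(c(m0$intercept, m0$coefficients[names(prob$X)])),
               unname(ols), tolerance = 1e-6)
  # full shrinkage
  mbig <- fit_lasso(prob$X, prob$y, 1e4)
  expect_true(all(mbig$coefficients == 0))
  expect_equal(mbig$intercept, mean(prob$y))
  # single standardized predictor: soft thresholding
  withr::with_seed(5, {
    z <- rnorm(90)
    z <- (z - mean(z)) / sqrt(mean((z - mean(z))^2))
    yy <- 0.8 * z + rnorm(90, sd = 0.4)
  })
  b_ols <- mean(z * yy)
  for (lam in c(0.05, 0.3, 2)) {
    m <- fit_lasso(tibble::tibble(z = z), yy, lam)
    expect_equal(unname(m$coefficients[["z"]]),
                 sign(b_ols) * max(abs(b_ols) - lam, 0), tolerance = 1e-8)
  }
})

test_that("component-wise boosting behaves as L2Boost", {
  prob <- linear_pmd_problem(60, p = 5, r2 = 0.8, seed = 6)
  # zero iterations: intercept-only
  m0 <- boost_componentwise(prob$X, prob$y, 0)
  expect_equal(unique(predict_pmd(m0, prob$X)), mean(prob$y))
  # one predictor, one full-step iteration equals simple OLS
  x1 <- prob$X[, "f01"]
  m1 <- boost_componentwise(x1, prob$y, n_iter = 1, step = 1)
  ols1 <- coef(lm(prob$y ~ prob$X$f01))
  expect_equal(unname(c(m1$intercept, m1$coefficients)), unname(ols1),
               tolerance = 1e-9)
  # orthonormal design: convergence to the OLS solution
  withr::with_seed(7, {
    q <- qr.Q(qr(matrix(rnorm(50 * 5), 50, 5)))
  })
  colnames(q) <- paste0("q", 1:5)
  Xq <- tibble::as_tibble(as.data.frame(q))
  yq <- as.numeric(q %*% c(3, -2, 1, 0.5, -0.25)) +
    withr::with_seed(8, rnorm(50, sd = 0.1))
  mb <- boost_componentwise(Xq, yq, n_iter = 5000, step = 0.1)
  olsq <- coef(lm(yq ~ q))
  expect_lt(max(abs(c(mb$intercept, mb$coefficients) - olsq)), 1e-3)
  # training MSE is non-increasing in iterations
  mse_it <- vapply(c(0, 5, 20, 100), function(k) {
    m <- boost_componentwise(prob$X, prob$y, k)
    mean((prob$y - predict_pmd(m, prob$X))^2)
  }, numeric(1))
  expect_true(all(diff(mse_it) <= 1e-12))
})

test_that("the boosting path reproduces direct fits on held-out data", {
  prob <- linear_pmd_problem(80, p = 6, r2 = 0.7, seed = 9)
  tr <- 1:60; te <- 61:80
  grid <- c(1, 5, 17, 40)
  path_pred <- mammotex:::boost_path_predictions(
    prob$X[tr, ], prob$y[tr], prob$X[te, ], grid)
  for (gi in seq_along(grid)) {
    m <- boost_componentwise(prob$X[tr, ], prob$y[tr], grid[gi])
    expect_equal(path_pred[, gi], predict_pmd(m, prob$X[te, ]),
                 tolerance = 1e-10)
  }
})

test_that("random forests fit signal and are seed-stable", {
  # constant response
  Xc <- noise_features(30, 3, seed = 10)
  mc <- suppressWarnings( # randomForest flags the constant response
    fit_forest(Xc, rep(5, 30), mtry = 2, n_trees = 50, seed = 1))
  expect_equal(predict_pmd(mc, Xc), rep(5, 30), tolerance = 1e-9)
  # step-function signal
  withr::with_seed(11, {
    X <- noise_features(500, 5, seed = 111)
    y <- ifelse(X$f01 > 0, 10, -10) + rnorm(500, sd = 1)
  })
  m <- fit_forest(X, y, mtry = 2, n_trees = 200, seed = 2)
  expect_gt(1 - m$oob_mse / var(y), 0.8)
  # same seed reproduces; different seeds stay within 10% OOB MSE
  m_same <- fit_forest(X, y, mtry = 2, n_trees = 200, seed = 2)
  expect_equal(m$oob_mse, m_same$oob_mse)
  m_other <- fit_forest(X, y, mtry = 2, n_trees = 200, seed = 3)
  expect_false(identical(m$forest, m_other$forest))
  expect_lt(abs(m$oob_mse - m_other$oob_mse) / m$oob_mse, 0.10)
  # forest predictions stay within the training response range
  expect_true(all(predict_pmd(m, X) >= min(y) & predict_pmd(m, X) <= max(y)))
})

test_that("tuning selects sensible lambdas and respects ties", {
  prob <- linear_pmd_problem(100, p = 10, r2 = 0.9, seed = 12)
  # one-point grid
  t1 <- tune_lambda(prob$X, prob$y, "lasso", grid = 0.3, folds = 5, seed = 1)
  expect_equal(t1$best_lambda, 0.3)
  # near-noiseless linear signal: small penalty wins, refit is excellent
  prob2 <- linear_pmd_problem(200, p = 10, r2 = 0.999, seed = 13)
  t2 <- tune_lambda(prob2$X, prob2$y, "lasso", folds = 5, seed = 1)
  m2 <- fit_lasso(prob2$X, prob2$y, t2$best_lambda)
  r2 <- 1 - mean((prob2$y - predict_pmd(m2, prob2$X))^2) / var(prob2$y)
  expect_gt(r2, 0.99)
  expect_equal(t2$best_lambda, min(t2$grid[t2$cv_mse == min(t2$cv_mse)]))
})

test_that("univariate cross-validation error grows with k on pure noise", {
  rhos <- vapply(1:10, function(s) {
    X <- noise_features(100, 40, seed = 1000 + s)
    y <- withr::with_seed(2000 + s, rnorm(100))
    tr <- tune_lambda(X, y, "univariate", grid = c(1, 2, 5, 10, 20, 35),
                      folds = 5, seed = s)
    suppressWarnings(cor(tr$grid, tr$cv_mse, method = "spearman"))
  }, numeric(1))
  expect_gt(mean(rhos), 0)
})

test_that("tuned lasso and boosting recover the designed R-squared regime", {
  prob <- linear_pmd_problem(1200, p = 50, r2 = 0.7, seed = 14)
  tr <- 1:400; te <- 401:1200
  for (method in c("lasso", "boosting")) {
    grid <- if (method == "boosting") c(25, 50, 100, 200, 400, 800) else NULL
    tune <- tune_lambda(prob$X[tr, ], prob$y[tr], method, grid = grid,
                        folds = 10, seed = 3)
    m <- fit_pmd_model(prob$X[tr, ], prob$y[tr], method, tune$best_lambda)
    pred <- predict_pmd(m, prob$X[te, ])
    r2 <- 1 - mean((prob$y[te] - pred)^2) / var(prob$y[te])
    expect_gt(r2, 0.65)
    expect_lt(r2, 0.75)
  }
})

test_that("prediction demands the features the model references", {
  prob <- linear_pmd_problem(50, p = 4, r2 = 0.8, seed = 15)
  m <- fit_lasso(prob$X, prob$y, 0.01)
  used <- names(which(m$coefficients != 0))
  expect_gt(length(used), 0)
  X_missing <- prob$X[, setdiff(names(prob$X), used[1])]
  expect_error(predict_pmd(m, X_missing), used[1])
  # fitted values on training data match the linear predictor exactly
  m0 <- fit_top_k(prob$X, prob$y, 4)
  fitted_lm <- unname(fitted(lm(prob$y ~ as.matrix(prob$X))))
  expect_equal(predict_pmd(m0, prob$X), fitted_lm, tolerance = 1e-9)
})

test_that("tidiers expose coefficients and metadata", {
  prob <- linear_pmd_problem(60, p = 4, r2 = 0.8, seed = 16)
  m <- fit_lasso(prob$X, prob$y, 0.05)
  td <- tidy(m)
  expect_equal(td$term[1], "(Intercept)")
  expect_true(all(td$estimate[-1] != 0))
  gl <- glance(m)
  expect_equal(gl$method, "lasso")
  expect_equal(gl$n_selected, nrow(td) - 1)
})
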