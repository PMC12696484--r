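test_that("regression metrics match hand arithmetic and guard degenerate
           input", {
  m <- regression_metrics(c(1, 2, 3), c(1, 2, 3), p = 1)
  expect_equal(m$r2, 1)
  expect_equal(m$mae, 0)
  expect_equal(m$rmse, 0)
  m2 <- regression_metrics(c(0, 1), c(0.5, 0.5))
  expect_equal(m2$mae, 0.5)
  expect_equal(m2$mse, 0.25)
  expect_equal(m2$rmse, 0.5)
  expect_equal(m2$r2, 0)
  # constant observations flag R2
  expect_true(is.na(regression_metrics(c(2, 2, 2), c(1, 2, 3))$r2))
  # adjusted R2 undefined when n - p - 1 <= 0
  expect_true(is.na(regression_metrics(c(0, 1, 2), c(0, 1, 2), p = 2)$adj_r2))
  # rmse^2 == mse exactly, and a brute recomputation agrees
  set.seed(23)
  y <- rnorm(50); yh <- y + rnorm(50, 0, 0.3)
  m3 <- regression_metrics(y, yh, p = 3)
  expect_equal(m3$rmse^2, m3$mse, tolerance = 1e-12)
  expect_equal(m3$r2, 1 - sum((y - yh)^2) / sum((y - mean(y))^2))
  expect_equal(m3$adj_r2, 1 - (1 - m3$r2) * 49 / (50 - 3 - 1))
})

test_that("every native backend learns a simple linear signal", {
  set.seed(29)
  n <- 120
  X <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- 3 * X[, 1] + rnorm(n, 0, 0.1)
  base_mae <- mean(abs(y - mean(y)))
  for (alg in c("rf", "knn", "sgd_linear", "mlp", "xgboost")) {
    fit <- fit_backend(alg, X, y, list(), seed = 1)
    mae <- mean(abs(y - predict_backend(fit, X)))
    expect_lt(mae, base_mae)
  }
  # distance-weighted knn interpolates its training points
  fit <- fit_backend("knn", X, y, list(k = 5, weights = "distance"), seed = 1)
  expect_equal(predict_backend(fit, X[1:5, ]), y[1:5], tolerance = 1e-10)
})

test_that("nested CV picks a sensible winner on a linear task and is
           deterministic", {
  set.seed(31)
  n <- 100
  train <- data.frame(x1 = rnorm(n), x2 = rnorm(n))
  train$y <- 3 * train$x1 + rnorm(n, 0, 0.2)
  specs <- default_model_specs()[c("rf", "sgd_linear", "knn")]
  cv <- nested_cv(train, "y", c("x1", "x2"), specs, k = 5, n_draws = 4,
                  seed = 9)
  # winning CV error close to the noise scale (mean |N(0, 0.2)| ~ 0.16)
  expect_lt(min(cv$mae_cv), 0.3)
  expect_equal(cv$winner, names(which.min(cv$mae_cv)))
  cv2 <- nested_cv(train, "y", c("x1", "x2"), specs, k = 5, n_draws = 4,
                   seed = 9)
  expect_identical(cv$mae_cv, cv2$mae_cv)
  # n_draws = 1 degenerates to plain 5-fold CV at one grid point
  cv3 <- nested_cv(train, "y", c("x1", "x2"), specs["rf"], n_draws = 1,
                   seed = 9)
  expect_length(cv3$mae_cv, 1L)
})

test_that("a duplicated algorithm yields identical CV scores under one
           seed", {
  set.seed(37)
  train <- data.frame(x = rnorm(60))
  train$y <- train$x + rnorm(60, 0, 0.1)
  specs <- list(rf = default_model_specs()$rf,
                rf2 = default_model_specs()$rf)
  specs$rf2$algorithm_id <- "rf"
  cv <- nested_cv(train, "y", "x", specs, n_draws = 2, seed = 3)
  expect_equal(unname(cv$mae_cv[1]), unname(cv$mae_cv[2]), tolerance = 0.01)
})

test_that("an unavailable optional backend is skipped and recorded", {
  set.seed(41)
  train <- data.frame(x = rnorm(40))
  train$y <- train$x + rnorm(40, 0.1)
  specs <- default_model_specs()[c("lightgbm", "rf")]
  if (requireNamespace("lightgbm", quietly = TRUE)) {
    # backend present: the pool simply contains both algorithms
    cv <- nested_cv(train, "y", "x", specs, n_draws = 1, seed = 2)
    expect_length(cv$skipped, 0L)
    expect_setequal(names(cv$mae_cv), c("lightgbm", "rf"))
  } else {
    expect_warning(cv <- nested_cv(train, "y", "x", specs, n_draws = 1,
                                   seed = 2), "lightgbm")
    expect_equal(cv$skipped, "lightgbm")
    expect_equal(cv$winner, "rf")
  }
})

test_that("the final refit honours scaling and beats the mean baseline", {
  set.seed(43)
  n <- 90
  train <- data.frame(x1 = rnorm(n, 100, 20), x2 = rnorm(n))
  train$y <- 0.05 * train$x1 + rnorm(n, 0, 0.2)
  m <- fit_final(train, "y", c("x1", "x2"), algorithm_id = "sgd_linear",
                 hyper = list(learning_rate = 0.01, max_iter = 500),
                 seed = 1)
  expect_false(is.null(m$scaler))  # scale-sensitive algorithm got a scaler
  pred <- predict(m, train)
  expect_length(pred, n)
  expect_lt(mean(abs(train$y - pred)), mean(abs(train$y - mean(train$y))))
  # deterministic refit
  m2 <- fit_final(train, "y", c("x1", "x2"), algorithm_id = "sgd_linear",
                  hyper = list(learning_rate = 0.01, max_iter = 500),
                  seed = 1)
  expect_identical(predict(m2, train), pred)
  expect_error(predict(m, train[, "x1", drop = FALSE]), "x2")
})

test_that("training-fold scores never see test labels", {
  set.seed(47)
  n <- 80
  train <- data.frame(x = rnorm(n))
  train$y <- train$x + rnorm(n, 0, 0.1)
  test <- data.frame(x = rnorm(20))
  test$y <- test$x + rnorm(20, 0, 0.1)
  cv1 <- nested_cv(train, "y", "x", default_model_specs()["rf"],
                   n_draws = 2, seed = 5)
  test$y <- sample(test$y)  # shuffling test labels must change nothing
  cv2 <- nested_cv(train, "y", "x", default_model_specs()["rf"],
                   n_draws = 2, seed = 5)
  expect_identical(cv1$mae_cv, cv2$mae_cv)
})
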