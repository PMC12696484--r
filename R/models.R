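#' Model specifications and hyperparameter grids
#'
#' Six regression algorithms are compared: random forest (`rf`, ranger
#' backend), k-nearest neighbours (`knn`), a linear model trained by
#' stochastic gradient descent (`sgd_linear`), a one-hidden-layer
#' perceptron (`mlp`), LightGBM (`lightgbm`, optional backend) and XGBoost
#' (`xgboost`). Each spec carries a randomised-search grid and a
#' `needs_scaling` flag; only the distance-based and linear learners (knn,
#' sgd_linear) are scaled, and the flag is honoured in every fit/predict
#' path. Grid entries are either `list(type = "int"|"num"|"lognum", lo, hi)`
#' ranges or vectors of categorical choices.
#'
#' @param algorithm_id one of `rf`, `knn`, `sgd_linear`, `mlp`,
#'   `lightgbm`, `xgboost`.
#' @param grid named list of hyperparameter ranges/choices (non-empty).
#' @param needs_scaling logical.
#' @return A `model_spec`.
#' @export
model_spec <- function(algorithm_id, grid, needs_scaling = FALSE) {
  stopif(length(grid) == 0L, "hyperparameter grid must be non-empty")
  structure(list(algorithm_id = algorithm_id, grid = grid,
                 needs_scaling = needs_scaling),
            class = "model_spec")
}

#' @rdname model_spec
#' @export
default_model_specs <- function() {
  list(
    rf = model_spec("rf", list(
      num_trees = list(type = "int", lo = 50, hi = 500),
      max_depth = list(type = "int", lo = 3, hi = 20),
      min_node_size = list(type = "int", lo = 2, hi = 10)
    ), needs_scaling = FALSE),
    knn = model_spec("knn", list(
      k = list(type = "int", lo = 2, hi = 15),
      weights = c("uniform", "distance")
    ), needs_scaling = TRUE),
    sgd_linear = model_spec("sgd_linear", list(
      learning_rate = list(type = "lognum", lo = 1e-4, hi = 1e-1),
      max_iter = list(type = "int", lo = 200, hi = 2000)
    ), needs_scaling = TRUE),
    mlp = model_spec("mlp", list(
      activation = c("relu", "tanh"),
      learning_rate = list(type = "lognum", lo = 1e-4, hi = 1e-2)
    ), needs_scaling = FALSE),
    lightgbm = model_spec("lightgbm", list(
      num_trees = list(type = "int", lo = 50, hi = 500),
      learning_rate = list(type = "lognum", lo = 0.01, hi = 0.3)
    ), needs_scaling = FALSE),
    xgboost = model_spec("xgboost", list(
      learning_rate = list(type = "lognum", lo = 0.01, hi = 0.3),
      max_depth = list(type = "int", lo = 2, hi = 10)
    ), needs_scaling = FALSE)
  )
}

sample_hyper <- function(grid, n_draws, seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  lapply(seq_len(n_draws), function(k) {
    lapply(grid, function(g) {
      if (is.list(g)) {
        switch(g$type,
               int = sample(seq(g$lo, g$hi), 1L),
               num = stats::runif(1, g$lo, g$hi),
               lognum = exp(stats::runif(1, log(g$lo), log(g$hi))))
      } else g[sample.int(length(g), 1L)]
    })
  })
}

# ---- backends ------------------------------------------------------------

fit_backend <- function(algorithm_id, X, y, hyper, seed) {
  X <- as.matrix(X)
  # backends seed their own RNG; never disturb the caller's stream
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  switch(algorithm_id,
    rf = list(kind = "rf",
              fit = ranger::ranger(
                x = X, y = y,
                num.trees = hyper$num_trees %||% 300,
                max.depth = hyper$max_depth %||% 0,
                min.node.size = hyper$min_node_size %||% 5,
                seed = seed, num.threads = 1)),
    knn = list(kind = "knn", X = X, y = y, k = hyper$k %||% 5,
               weights = hyper$weights %||% "uniform"),
    sgd_linear = fit_sgd_linear(X, y,
                                lr = hyper$learning_rate %||% 0.01,
                                max_iter = hyper$max_iter %||% 1000,
                                seed = seed),
    mlp = fit_mlp(X, y, activation = hyper$activation %||% "relu",
                  lr = hyper$learning_rate %||% 1e-3, seed = seed),
    lightgbm = {
      if (!requireNamespace("lightgbm", quietly = TRUE))
        stop("backend_unavailable: lightgbm is not installed")
      list(kind = "lightgbm",
           fit = lightgbm::lightgbm(
             data = X, label = y,
             params = list(objective = "regression",
                           learning_rate = hyper$learning_rate %||% 0.1,
                           num_threads = 1, verbosity = -1,
                           seed = seed),
             nrounds = hyper$num_trees %||% 200, verbose = -1))
    },
    xgboost = {
      set.seed(seed)
      list(kind = "xgboost",
           fit = xgboost::xgboost(
             x = X, y = y, nrounds = 150,
             learning_rate = hyper$learning_rate %||% 0.1,
             max_depth = hyper$max_depth %||% 6,
             nthreads = 1, verbosity = 0,
             objective = "reg:squarederror"))
    },
    stop("unknown algorithm: ", algorithm_id)
  )
}

predict_backend <- function(fit, X) {
  X <- as.matrix(X)
  switch(fit$kind,
    rf = stats::predict(fit$fit, data = as.data.frame(X),
                        num.threads = 1)$predictions,
    knn = {
      tr <- fit$X
      apply(X, 1, function(q) {
        d <- sqrt(colSums((t(tr) - q)^2))
        ord <- order(d)[seq_len(min(fit$k, length(d)))]
        if (fit$weights == "uniform") mean(fit$y[ord]) else {
          dd <- d[ord]
          if (any(dd < 1e-12)) mean(fit$y[ord][dd < 1e-12]) else {
            w <- 1 / dd
            sum(w * fit$y[ord]) / sum(w)
          }
        }
      })
    },
    sgd = as.numeric(cbind(1, X) %*% fit$coef),
    mlp = predict_mlp(fit, X),
    lightgbm = stats::predict(fit$fit, X),
    xgboost = stats::predict(fit$fit, X),
    stop("unknown fit kind")
  )
}

# Plain stochastic gradient descent on squared loss, constant learning rate,
# one pass over a shuffled row order per iteration ("max_iter" = epochs).
fit_sgd_linear <- function(X, y, lr, max_iter, seed) {
  set.seed(seed)
  n <- nrow(X); p <- ncol(X)
  w <- numeric(p + 1)
  for (it in seq_len(max_iter)) {
    for (i in sample.int(n)) {
      xi <- c(1, X[i, ])
      g <- 2 * (sum(w * xi) - y[i]) * xi
      w <- w - lr * g
      if (any(!is.finite(w))) return(list(kind = "sgd", coef = rep(0, p + 1)))
    }
    if (it >= 3L && it %% 50L == 0L && max(abs(g)) < 1e-8) break
  }
  list(kind = "sgd", coef = w)
}

# One-hidden-layer perceptron (32 units), relu or tanh, trained full-batch
# with Adam on squared loss.
fit_mlp <- function(X, y, activation, lr, seed, hidden = 32L,
                    epochs = 300L) {
  set.seed(seed)
  n <- nrow(X); p <- ncol(X)
  act <- if (activation == "relu") function(z) pmax(z, 0) else tanh
  dact <- if (activation == "relu") function(z) (z > 0) * 1 else
    function(z) 1 - tanh(z)^2
  W1 <- matrix(stats::rnorm(p * hidden, sd = sqrt(2 / max(1, p))), p, hidden)
  b1 <- numeric(hidden)
  W2 <- matrix(stats::rnorm(hidden, sd = sqrt(1 / hidden)), hidden, 1)
  b2 <- 0
  ms <- list(W1 = 0 * W1, b1 = b1 * 0, W2 = 0 * W2, b2 = 0)
  vs <- ms
  b1m <- 0.9; b2m <- 0.999; eps <- 1e-8
  for (t in seq_len(epochs)) {
    Z1 <- sweep(X %*% W1, 2, b1, "+")
    H <- act(Z1)
    yhat <- as.numeric(H %*% W2 + b2)
    err <- yhat - y
    gW2 <- t(H) %*% (2 * err / n)
    gb2 <- sum(2 * err / n)
    dH <- (2 * err / n) %*% t(W2) * dact(Z1)
    gW1 <- t(X) %*% dH
    gb1 <- colSums(dH)
    grads <- list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2)
    for (nm in names(grads)) {
      ms[[nm]] <- b1m * ms[[nm]] + (1 - b1m) * grads[[nm]]
      vs[[nm]] <- b2m * vs[[nm]] + (1 - b2m) * grads[[nm]]^2
      mhat <- ms[[nm]] / (1 - b1m^t)
      vhat <- vs[[nm]] / (1 - b2m^t)
      step <- lr * mhat / (sqrt(vhat) + eps)
      if (nm == "W1") W1 <- W1 - step
      if (nm == "b1") b1 <- b1 - as.numeric(step)
      if (nm == "W2") W2 <- W2 - step
      if (nm == "b2") b2 <- b2 - as.numeric(step)
    }
  }
  list(kind = "mlp", W1 = W1, b1 = b1, W2 = W2, b2 = b2,
       activation = activation)
}

predict_mlp <- function(fit, X) {
  act <- if (fit$activation == "relu") function(z) pmax(z, 0) else tanh
  H <- act(sweep(as.matrix(X) %*% fit$W1, 2, fit$b1, "+"))
  as.numeric(H %*% fit$W2 + fit$b2)
}

# ---- nested cross-validation --------------------------------------------

#' Nested k-fold cross-validation with randomised search
#'
#' For each algorithm spec, `n_draws` hyperparameter combinations are
#' sampled and evaluated by k-fold cross-validation on the training table;
#' folds are shared across algorithms under the master seed, and scaling
#' for scale-sensitive algorithms is refit inside every fold (no leakage).
#' The winner is the algorithm/combination with the lowest mean validation
#' MAE. Backends whose optional dependency is missing are skipped with a
#' warning and recorded.
#'
#' @param train data.frame of training rows.
#' @param target name of the response column.
#' @param features character vector of feature columns.
#' @param specs list of [model_spec()]s; default [default_model_specs()].
#' @param k number of folds (default 5).
#' @param n_draws randomised-search draws per algorithm (default 25).
#' @param seed master seed; fold assignment and each draw derive from it.
#' @return A `cv_result`: per-algorithm table (`algorithm`, `mae_cv`,
#'   best hyperparameters), `winner`, `folds`, `skipped`.
#' @export
nested_cv <- function(train, target, features,
                      specs = default_model_specs(), k = 5, n_draws = 25,
                      seed = 1L) {
  stopif(n_draws < 1, "n_draws must be >= 1")
  stopif(nrow(train) < k, "need at least k training rows")
  y <- train[[target]]
  X <- train[, features, drop = FALSE]
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(derive_seed(seed, "folds"))
  folds <- sample(rep(seq_len(k), length.out = nrow(train)))

  results <- list(); skipped <- character(); algo_of <- character()
  for (si in seq_along(specs)) {
    spec <- specs[[si]]
    nm <- names(specs)[si] %||% spec$algorithm_id
    if (is.null(names(specs)) || nm == "") nm <- spec$algorithm_id
    draws <- sample_hyper(spec$grid, n_draws,
                          derive_seed(seed, "cv") +
                            match(spec$algorithm_id,
                                  vapply(specs, `[[`, "", "algorithm_id")))
    best <- NULL
    for (di in seq_along(draws)) {
      hyper <- draws[[di]]
      maes <- numeric(k)
      failed <- FALSE
      for (f in seq_len(k)) {
        tr <- folds != f; va <- !tr
        Xtr <- X[tr, , drop = FALSE]; Xva <- X[va, , drop = FALSE]
        if (spec$needs_scaling) {
          sc <- suppressWarnings(fit_scaler(Xtr))
          Xtr <- scale_apply(sc, Xtr); Xva <- scale_apply(sc, Xva)
        }
        fit <- tryCatch(
          fit_backend(spec$algorithm_id, Xtr, y[tr], hyper,
                      seed = derive_seed(seed, "model") + f + 97L * di),
          error = function(e) {
            if (grepl("backend_unavailable", conditionMessage(e))) NULL
            else stop(e)
          })
        if (is.null(fit)) { failed <- TRUE; break }
        maes[f] <- mean(abs(y[va] - predict_backend(fit, Xva)))
      }
      if (failed) break
      mae_cv <- mean(maes)
      if (is.null(best) || mae_cv < best$mae_cv)
        best <- list(mae_cv = mae_cv, hyper = hyper)
    }
    if (is.null(best)) {
      warning("backend unavailable, skipping algorithm: ",
              spec$algorithm_id, call. = FALSE)
      skipped <- c(skipped, spec$algorithm_id)
      next
    }
    best$algorithm_id <- spec$algorithm_id
    results[[nm]] <- best
    algo_of[nm] <- spec$algorithm_id
  }
  stopif(length(results) == 0L, "no usable algorithm backend")
  maes <- vapply(results, `[[`, 0, "mae_cv")
  structure(list(results = results, mae_cv = maes,
                 winner = names(which.min(maes)), algorithm_of = algo_of,
                 folds = folds, skipped = skipped, seed = seed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("<cv_result> MAE_cv by algorithm:\n")
  for (nm in names(sort(x$mae_cv)))
    cat(sprintf("  %-11s %.4f%s\n", nm, x$mae_cv[nm],
                if (nm == x$winner) "  <- winner" else ""))
  if (length(x$skipped))
    cat("  skipped (backend unavailable):",
        paste(x$skipped, collapse = ", "), "\n")
  invisible(x)
}

#' Fit the winning model on the full training set
#'
#' Refits with the best hyperparameters; the returned `tuned_model` carries
#' the feature list and (when the algorithm is scale-sensitive) the scaler
#' fitted on the full training set, so `predict()` works on raw rows.
#'
#' @param train training data.frame.
#' @param target response column name.
#' @param features feature column names.
#' @param cv a [nested_cv()] result (or `NULL` with explicit
#'   `algorithm_id`/`hyper`).
#' @param algorithm_id,hyper override the CV winner.
#' @param seed integer seed for the refit.
#' @return A `tuned_model`.
#' @export
fit_final <- function(train, target, features, cv = NULL,
                      algorithm_id = NULL, hyper = NULL, seed = 1L) {
  if (is.null(algorithm_id)) {
    stopif(is.null(cv), "need a cv_result or an explicit algorithm_id")
    algorithm_id <- cv$results[[cv$winner]]$algorithm_id
    hyper <- cv$results[[cv$winner]]$hyper
  }
  specs <- default_model_specs()
  needs_scaling <- specs[[algorithm_id]]$needs_scaling
  X <- train[, features, drop = FALSE]
  scaler <- NULL
  if (needs_scaling) {
    scaler <- suppressWarnings(fit_scaler(X))
    X <- scale_apply(scaler, X)
  }
  fit <- fit_backend(algorithm_id, X, train[[target]], hyper %||% list(),
                     seed = derive_seed(seed, "model"))
  structure(list(algorithm_id = algorithm_id, hyper = hyper %||% list(),
                 fit = fit, features = features, target = target,
                 scaler = scaler, seed = seed),
            class = "tuned_model")
}

#' @export
predict.tuned_model <- function(object, newdata, ...) {
  stopif(!all(object$features %in% names(newdata)),
         "newdata missing feature column(s): ",
         paste(setdiff(object$features, names(newdata)), collapse = ", "))
  X <- newdata[, object$features, drop = FALSE]
  if (!is.null(object$scaler)) X <- scale_apply(object$scaler, X)
  predict_backend(object$fit, X)
}

#' @export
print.tuned_model <- function(x, ...) {
  cat("<tuned_model>", x$algorithm_id, "on", length(x$features),
      "features\n")
  if (length(x$hyper))
    cat("  hyper:", paste(names(x$hyper), unlist(x$hyper), sep = "=",
                          collapse = ", "), "\n")
  invisible(x)
}
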