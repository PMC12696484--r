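#' Leave-one-out cross-validated Q2
#'
#' `Q2_loo = 1 - sum (y_i - yhat_(-i))^2 / sum (y_i - ybar)^2` where
#' `yhat_(-i)` comes from a model refit without row i using the *same*
#' hyperparameters (no re-tuning per left-out point).
#'
#' @param train training data.frame (n >= 3).
#' @param target response column.
#' @param features feature columns.
#' @param algorithm_id,hyper the tuned model's algorithm and
#'   hyperparameters.
#' @param seed integer seed for the refits.
#' @return Q2_loo (scalar; `NA` with a warning when `SS_tot = 0`).
#' @export
loo_q2 <- function(train, target, features, algorithm_id, hyper = list(),
                   seed = 1L) {
  n <- nrow(train)
  stopif(n < 3L, "leave-one-out Q2 needs at least 3 rows")
  y <- train[[target]]
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) {
    warning("constant response: Q2_loo undefined", call. = FALSE)
    return(NA_real_)
  }
  preds <- numeric(n)
  for (i in seq_len(n)) {
    m <- fit_final(train[-i, , drop = FALSE], target, features,
                   algorithm_id = algorithm_id, hyper = hyper, seed = seed)
    preds[i] <- predict(m, train[i, , drop = FALSE])
  }
  1 - sum((y - preds)^2) / ss_tot
}

#' Golbraikh-Tropsha acceptability criteria
#'
#' External-predictivity checks on observed (y) vs predicted (yhat) values:
#' through-origin slopes `k = sum(y yhat) / sum(yhat^2)` and
#' `k' = sum(y yhat) / sum(y^2)`, through-origin determination coefficients
#' `r0^2` (regressing y on k*yhat) and `r0'^2` (yhat on k'*y), the squared
#' Pearson correlation `r^2`, and the ratios `(r^2 - r0^2)/r^2` in both
#' directions. The model passes when `r^2 > 0.6`, `Q2_loo > 0.5`, at least
#' one ratio is `< 0.1` and at least one slope lies in `(0.85, 1.15)`; each
#' flag is reported individually.
#'
#' @param y observed values (n >= 3, nonconstant).
#' @param yhat predicted values.
#' @param q2_loo optional Q2_loo to fold into the overall verdict.
#' @return A `gt_report` list of all quantities and pass flags.
#' @export
golbraikh_tropsha <- function(y, yhat, q2_loo = NA) {
  stopif(length(y) != length(yhat), "length mismatch")
  stopif(length(y) < 3L, "need at least 3 observations")
  undef <- function(d) abs(d) < 1e-300
  r2 <- suppressWarnings(stats::cor(y, yhat)^2)
  k <- if (undef(sum(yhat^2))) NA_real_ else sum(y * yhat) / sum(yhat^2)
  kp <- if (undef(sum(y^2))) NA_real_ else sum(y * yhat) / sum(y^2)
  ss_y <- sum((y - mean(y))^2)
  ss_yh <- sum((yhat - mean(yhat))^2)
  r02 <- if (undef(ss_y) || is.na(k)) NA_real_ else
    1 - sum((y - k * yhat)^2) / ss_y
  r02p <- if (undef(ss_yh) || is.na(kp)) NA_real_ else
    1 - sum((yhat - kp * y)^2) / ss_yh
  ratio1 <- if (is.na(r2) || r2 == 0) NA_real_ else (r2 - r02) / r2
  ratio2 <- if (is.na(r2) || r2 == 0) NA_real_ else (r2 - r02p) / r2
  flags <- list(
    r2_gt_0.6 = isTRUE(r2 > 0.6),
    q2_loo_gt_0.5 = isTRUE(q2_loo > 0.5),
    ratio_lt_0.1 = isTRUE(ratio1 < 0.1) || isTRUE(ratio2 < 0.1),
    slope_in_window = isTRUE(k > 0.85 && k < 1.15) ||
      isTRUE(kp > 0.85 && kp < 1.15)
  )
  structure(list(r2 = r2, q2_loo = q2_loo, k = k, k_prime = kp,
                 r02 = r02, r02_prime = r02p, ratio = ratio1,
                 ratio_prime = ratio2, flags = flags,
                 pass = all(unlist(flags))),
            class = "gt_report")
}

#' @export
print.gt_report <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "NA" else sprintf("%.4f", v)
  cat("<gt_report>\n")
  cat("  r2 =", fmt(x$r2), " Q2_loo =", fmt(x$q2_loo), "\n")
  cat("  k =", fmt(x$k), " k' =", fmt(x$k_prime), "\n")
  cat("  (r2-r02)/r2 =", fmt(x$ratio), " (r2-r0'2)/r2 =",
      fmt(x$ratio_prime), "\n")
  for (nm in names(x$flags))
    cat("  ", nm, ":", if (x$flags[[nm]]) "pass" else "FAIL", "\n")
  cat("  overall:", if (x$pass) "PASS" else "FAIL", "\n")
  invisible(x)
}

#' Y-scrambling robustness test
#'
#' Permutes the response within the training set `n_rounds` times, refits
#' with identical hyperparameters, and evaluates each scrambled model on
#' the untouched test rows. A real model should beat every scrambled round.
#'
#' @param train,test data.frames.
#' @param target,features,algorithm_id,hyper as in [loo_q2()].
#' @param n_rounds number of randomisations (default 5).
#' @param seed integer seed.
#' @return list with `true` (R2/MAE of the unscrambled model), `rounds`
#'   (per-round R2/MAE), and `verdict` (`"degraded"` when the true R2
#'   exceeds every scrambled R2, else `"indistinguishable"`).
#' @export
y_scramble <- function(train, test, target, features, algorithm_id,
                       hyper = list(), n_rounds = 5, seed = 1L) {
  if (n_rounds == 0)
    return(list(true = NULL, rounds = NULL, verdict = NA_character_))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(derive_seed(seed, "scramble"))
  y_test <- test[[target]]
  true_model <- fit_final(train, target, features,
                          algorithm_id = algorithm_id, hyper = hyper,
                          seed = seed)
  mt <- regression_metrics(y_test, predict(true_model, test))
  rounds <- lapply(seq_len(n_rounds), function(r) {
    scr <- train
    scr[[target]] <- sample(scr[[target]])
    m <- fit_final(scr, target, features, algorithm_id = algorithm_id,
                   hyper = hyper, seed = seed)
    regression_metrics(y_test, predict(m, test))
  })
  scr_r2 <- vapply(rounds, `[[`, 0, "r2")
  verdict <- if (all(mt$r2 > scr_r2)) "degraded" else "indistinguishable"
  list(true = mt, rounds = rounds, scrambled_r2 = scr_r2, verdict = verdict)
}

#' Bootstrap out-of-bag confidence intervals
#'
#' Resamples the table with replacement `B` times, refits with the same
#' hyperparameters, scores each refit on its out-of-bag rows, and reports
#' percentile confidence intervals for MAE and R2. Resamples with an empty
#' out-of-bag set are skipped and counted; rows never out-of-bag are
#' reported.
#'
#' @param table data.frame to resample.
#' @param target,features,algorithm_id,hyper model definition.
#' @param B number of resamples (>= 50; default 1000).
#' @param level confidence level (default 0.95).
#' @param seed integer seed.
#' @return list with `point` (full-data out-of-sample-free metrics are not
#'   reported here; `point` holds the mean over resamples), `ci_mae`,
#'   `ci_r2`, `skipped`, `never_oob`.
#' @export
bootstrap_ci <- function(table, target, features, algorithm_id,
                         hyper = list(), B = 1000, level = 0.95, seed = 1L) {
  stopif(B < 50, "B must be at least 50")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(derive_seed(seed, "bootstrap"))
  n <- nrow(table)
  maes <- numeric(0); r2s <- numeric(0); skipped <- 0L
  oob_seen <- rep(FALSE, n)
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    oob <- setdiff(seq_len(n), idx)
    if (length(oob) < 2L) { skipped <- skipped + 1L; next }
    oob_seen[oob] <- TRUE
    m <- fit_final(table[idx, , drop = FALSE], target, features,
                   algorithm_id = algorithm_id, hyper = hyper, seed = seed)
    met <- regression_metrics(table[[target]][oob],
                              predict(m, table[oob, , drop = FALSE]))
    maes <- c(maes, met$mae); r2s <- c(r2s, met$r2)
  }
  a <- (1 - level) / 2
  qs <- function(x) unname(stats::quantile(x, c(a, 1 - a), na.rm = TRUE))
  list(point = list(mae = mean(maes), r2 = mean(r2s, na.rm = TRUE)),
       ci_mae = qs(maes), ci_r2 = qs(r2s), level = level,
       skipped = skipped, never_oob = which(!oob_seen), B = B)
}
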