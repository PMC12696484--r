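#' Regression performance metrics
#'
#' `R2 = 1 - SS_res / SS_tot`, adjusted
#' `R2_adj = 1 - (1 - R2) (n - 1) / (n - p - 1)`, plus MAE, MSE and
#' `RMSE = sqrt(MSE)` exactly. Constant observations (`SS_tot = 0`) flag R2
#' as `NA`; `n - p - 1 <= 0` flags the adjusted R2.
#'
#' @param y observed values.
#' @param yhat predicted values, same length.
#' @param p number of model features (for the adjusted R2); default `NA`
#'   skips the adjustment.
#' @return named list: `r2`, `adj_r2`, `mae`, `mse`, `rmse`, `n`.
#' @export
regression_metrics <- function(y, yhat, p = NA) {
  stopif(length(y) != length(yhat), "y and yhat lengths differ")
  stopif(length(y) < 2L, "need at least two observations")
  n <- length(y)
  res <- y - yhat
  ss_res <- sum(res^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) NA_real_ else 1 - ss_res / ss_tot
  adj <- if (is.na(p) || n - p - 1 <= 0 || is.na(r2)) NA_real_ else
    1 - (1 - r2) * (n - 1) / (n - p - 1)
  mse <- mean(res^2)
  list(r2 = r2, adj_r2 = adj, mae = mean(abs(res)), mse = mse,
       rmse = sqrt(mse), n = n)
}
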