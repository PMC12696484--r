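#' Permutation-sampling Shapley attributions
#'
#' Marginal (interventional) Shapley values estimated by sampling feature
#' permutations against a background sample: for each permutation the
#' features of the explained row replace background values one at a time in
#' permutation order, and each feature is credited with the change in the
#' model output it causes. Antithetic permutation pairs (each permutation
#' and its reverse) reduce variance. By the telescoping construction the
#' per-row attributions sum *exactly* to
#' `prediction - base_value`, where `base_value` is the mean model output
#' over the background sample; this additivity holds at floating-point
#' precision for any model.
#'
#' The sign convention follows the modelled endpoint: positive attributions
#' push the predicted viability up (toward non-cytotoxicity), negative ones
#' toward cytotoxicity.
#'
#' @param predict_fun function taking a feature matrix/data.frame and
#'   returning numeric predictions.
#' @param X rows to explain (matrix or data.frame).
#' @param background background sample (defaults to `X`, subsampled to
#'   `max_background` rows).
#' @param n_perm number of sampled permutations (antithetic pairs count as
#'   two); default 64.
#' @param max_background background subsample cap.
#' @param seed integer seed.
#' @return list with `attributions` (rows x features matrix),
#'   `base_value`, and `prediction` (numeric vector).
#' @export
shap_sampling <- function(predict_fun, X, background = NULL, n_perm = 64,
                          max_background = 20, seed = 1L) {
  X <- as.data.frame(X)
  stopif(nrow(X) == 0L, "no rows to explain")
  p <- ncol(X)
  if (is.null(background)) background <- X
  background <- as.data.frame(background)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  if (nrow(background) > max_background)
    background <- background[sample.int(nrow(background), max_background), ,
                             drop = FALSE]
  nb <- nrow(background)
  n <- nrow(X)

  # permutations: antithetic pairs
  n_half <- max(1L, n_perm %/% 2L)
  perms <- vector("list", 2L * n_half)
  for (k in seq_len(n_half)) {
    pp <- sample.int(p)
    perms[[2L * k - 1L]] <- pp
    perms[[2L * k]] <- rev(pp)
  }

  pred_x <- as.numeric(predict_fun(X))
  base_each <- as.numeric(predict_fun(background))
  base_value <- mean(base_each)

  # start: every explained row paired with every background row
  phi <- matrix(0, n, p, dimnames = list(NULL, names(X)))
  rep_bg <- background[rep(seq_len(nb), times = n), , drop = FALSE]
  x_idx <- rep(seq_len(n), each = nb)
  prev_base <- rep(base_each, times = n)   # f(background) per hybrid row

  for (perm in perms) {
    hybrid <- rep_bg
    prev <- prev_base
    for (j in perm) {
      hybrid[[j]] <- X[[j]][x_idx]
      cur <- as.numeric(predict_fun(hybrid))
      delta <- cur - prev
      phi[, j] <- phi[, j] + as.numeric(rowsum(delta, x_idx)) / nb
      prev <- cur
    }
  }
  phi <- phi / length(perms)
  list(attributions = phi, base_value = base_value, prediction = pred_x)
}
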