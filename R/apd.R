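#' Weighted Gower distance for mixed feature types
#'
#' `d(x, y) = sum_k w_k d_k / sum_k w_k` with
#' `d_k = |x_k - y_k| / range_k` for numeric features (clipped at 1 for
#' out-of-range queries) and `d_k = 1{x_k != y_k}` for categoricals.
#' Zero-range numeric features are skipped with a warning (delta-style
#' exclusion). With normalised weights the distance lies in `[0, 1]`.
#'
#' @param x,y feature vectors (or single-row data.frames) of equal length.
#' @param weights non-negative feature weights, not all zero.
#' @param ranges numeric ranges per feature (ignored at categorical
#'   positions), learned on training data.
#' @param categorical logical mask marking categorical features.
#' @return scalar distance in `[0, 1]`.
#' @export
gower_distance <- function(x, y, weights = NULL, ranges = NULL,
                           categorical = NULL) {
  x <- unlist(x, use.names = FALSE); y <- unlist(y, use.names = FALSE)
  p <- length(x)
  stopif(length(y) != p, "x and y lengths differ")
  if (is.null(weights)) weights <- rep(1, p)
  if (is.null(categorical)) categorical <- rep(FALSE, p)
  stopif(any(weights < 0) || sum(weights) == 0,
         "weights must be non-negative and not all zero")
  d <- numeric(p)
  w <- weights
  for (k in seq_len(p)) {
    if (categorical[k]) {
      d[k] <- as.numeric(x[k] != y[k])
    } else {
      rng <- ranges[k]
      if (is.null(ranges) || !is.finite(rng) || rng == 0) {
        warning("zero or missing range for numeric feature ", k,
                "; feature skipped", call. = FALSE)
        w[k] <- 0
        next
      }
      d[k] <- min(1, abs(as.numeric(x[k]) - as.numeric(y[k])) / rng)
    }
  }
  stopif(sum(w) == 0, "all features skipped; cannot compute Gower distance")
  sum(w * d) / sum(w)
}

# distances from each row of Q to each row of R (rows x refs matrix)
gower_cross <- function(Q, R, weights, ranges, categorical) {
  Q <- as.data.frame(Q); R <- as.data.frame(R)
  p <- ncol(Q)
  w <- weights
  acc <- matrix(0, nrow(Q), nrow(R))
  wtot <- 0
  for (k in seq_len(p)) {
    if (categorical[k]) {
      dk <- outer(Q[[k]], R[[k]], "!=") * 1
    } else {
      if (!is.finite(ranges[k]) || ranges[k] == 0) next
      dk <- pmin(1, abs(outer(as.numeric(Q[[k]]), as.numeric(R[[k]]), "-")) /
                   ranges[k])
    }
    acc <- acc + w[k] * dk
    wtot <- wtot + w[k]
  }
  acc / wtot
}

euclid_cross <- function(Q, R) {
  Q <- as.matrix(Q); R <- as.matrix(R)
  # exact per-row differences (the expanded-square form loses exactness
  # for coincident rows)
  t(vapply(seq_len(nrow(Q)), function(i)
    sqrt(colSums((t(R) - Q[i, ])^2)), numeric(nrow(R))))
}

#' Fit a distance-based applicability domain
#'
#' All `n (n - 1) / 2` pairwise training distances are computed; those
#' strictly below their mean are retained, and the threshold is
#' `<d> + Z * sigma` with `<d>` and `sigma` (sample sd) taken over the
#' retained subset. With Euclidean distances categorical columns must be
#' excluded beforehand; the Gower metric handles mixed types and
#' feature-specific weights.
#'
#' @param train data.frame of training features (already encoded/scaled as
#'   used by the model; >= 3 rows).
#' @param metric `"euclidean"` or `"gower"`.
#' @param Z threshold multiplier (default 0.5).
#' @param weights optional Gower feature weights (default equal).
#' @param categorical logical mask of categorical columns (Gower only).
#' @return An `apd_model` with the reference matrix, `d_mean`, `d_sd`,
#'   `Z`, `threshold` and the Gower ranges/weights.
#' @export
fit_apd <- function(train, metric = c("euclidean", "gower"), Z = 0.5,
                    weights = NULL, categorical = NULL) {
  metric <- match.arg(metric)
  train <- as.data.frame(train)
  n <- nrow(train)
  stopif(n < 3L, "applicability domain needs at least 3 training rows")
  if (is.null(categorical)) categorical <- rep(FALSE, ncol(train))
  if (is.null(weights)) weights <- rep(1, ncol(train))
  stopif(metric == "euclidean" && any(!vapply(train, is.numeric, TRUE)),
         "euclidean APD requires numeric features only; ",
         "exclude categorical columns or use metric = \"gower\"")
  ranges <- vapply(seq_along(train), function(k) {
    if (categorical[k]) NA_real_ else diff(range(as.numeric(train[[k]])))
  }, 0)

  dm <- if (metric == "euclidean") euclid_cross(train, train) else
    gower_cross(train, train, weights, ranges, categorical)
  dvec <- dm[upper.tri(dm)]
  retained <- dvec[dvec < mean(dvec)]
  stopif(length(retained) < 2L,
         "degenerate distance distribution: no pairwise distances fall ",
         "strictly below their mean (all-equal distances?); the APD ",
         "threshold is undefined for this training set")
  d_mean <- mean(retained)
  d_sd <- stats::sd(retained)
  structure(list(metric = metric, reference = train, weights = weights,
                 ranges = ranges, categorical = categorical,
                 d_mean = d_mean, d_sd = d_sd, Z = Z,
                 threshold = d_mean + Z * d_sd),
            class = "apd_model")
}

#' @export
print.apd_model <- function(x, ...) {
  cat(sprintf(
    "<apd_model> metric=%s  <d>=%.4f  sigma=%.4f  Z=%.2f  threshold=%.4f\n",
    x$metric, x$d_mean, x$d_sd, x$Z, x$threshold))
  invisible(x)
}

#' Gate a query against the applicability domain
#'
#' A prediction is reliable iff the query's distance to its nearest
#' training neighbour does not exceed the threshold (inclusive: "exceeds"
#' is read strictly). For rows of the training set itself the nearest
#' *other* row is used.
#'
#' @param query one or more rows with the training feature columns.
#' @param apd a fitted [fit_apd()] model.
#' @param exclude_self drop exact-zero self-matches when querying training
#'   rows.
#' @return data.frame with `nearest_distance`, `threshold`, `reliable`.
#' @export
in_domain <- function(query, apd, exclude_self = FALSE) {
  query <- as.data.frame(query)
  miss <- setdiff(names(apd$reference), names(query))
  stopif(length(miss) > 0, "query missing feature column(s): ",
         paste(miss, collapse = ", "))
  query <- query[, names(apd$reference), drop = FALSE]
  dm <- if (apd$metric == "euclidean") euclid_cross(query, apd$reference)
    else gower_cross(query, apd$reference, apd$weights, apd$ranges,
                     apd$categorical)
  nd <- apply(dm, 1, function(r) {
    if (exclude_self) r <- r[r > 1e-12]
    if (length(r) == 0) 0 else min(r)
  })
  data.frame(nearest_distance = nd, threshold = apd$threshold,
             reliable = nd <= apd$threshold)
}
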