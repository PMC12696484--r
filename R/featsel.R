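#' Zero-variance and pairwise-correlation filter
#'
#' Drops constant columns, then scans feature pairs in the supplied column
#' order (the descriptor registry order), greedily dropping the *later*
#' member of any pair with `|r| > threshold` against a surviving earlier
#' member. The result depends on column order only, never row order.
#'
#' @param train training data.frame.
#' @param features feature columns to filter, in registry order.
#' @param threshold absolute Pearson correlation above which the later
#'   feature is dropped (default 0.99).
#' @return list with `kept`, `dropped_zero_variance`,
#'   `dropped_correlated` (data.frame feature/against/r).
#' @export
variance_correlation_filter <- function(train, features, threshold = 0.99) {
  stopif(nrow(train) < 2L, "need at least 2 training rows")
  X <- train[, features, drop = FALSE]
  sds <- vapply(X, stats::sd, 0)
  zero_var <- features[sds == 0 | !is.finite(sds)]
  surv <- setdiff(features, zero_var)
  dropped <- data.frame(feature = character(), against = character(),
                        r = numeric())
  keep <- character()
  for (f in surv) {
    r_with_kept <- vapply(keep, function(g)
      abs(suppressWarnings(stats::cor(X[[f]], X[[g]]))), 0)
    hit <- which(r_with_kept > threshold)
    if (length(hit)) {
      dropped <- rbind(dropped, data.frame(
        feature = f, against = keep[hit[1]],
        r = unname(r_with_kept[hit[1]])))
    } else {
      keep <- c(keep, f)
    }
  }
  list(kept = keep, dropped_zero_variance = zero_var,
       dropped_correlated = dropped)
}

#' SHAP-ranked selection of atomistic descriptors
#'
#' A random forest (40 trees, depth 10) is trained on the surviving
#' feature pool; per-instance Shapley attributions are aggregated to mean
#' absolute scores, the atomistic descriptors are ranked, and the top `k`
#' are united with the five fixed experimental features (core size,
#' coating group, shell material, shell thickness, concentration).
#' Selection uses training rows only, and ties break in registry order.
#'
#' @param train training data.frame.
#' @param target response column.
#' @param atomistic_features surviving atomistic descriptor ids (registry
#'   order).
#' @param experimental_features the fixed experimental set (default the
#'   five above).
#' @param k number of atomistic descriptors to keep (default 8).
#' @param n_perm,seed forwarded to [shap_sampling()].
#' @return A `feature_selection`: `final_set`, `shap_ranking`
#'   (data.frame), plus the inputs for the report.
#' @export
shap_rank_select <- function(train, target, atomistic_features,
                             experimental_features = c(
                               "core_diameter", "coating_group",
                               "shell_material", "shell_thickness",
                               "concentration"),
                             k = 8, n_perm = 32, seed = 1L) {
  stopif(nrow(train) < 20L, "SHAP selection needs at least 20 training rows")
  if (k > length(atomistic_features)) {
    warning("k exceeds the surviving atomistic pool (",
            length(atomistic_features), "); keeping all", call. = FALSE)
    k <- length(atomistic_features)
  }
  pool <- c(atomistic_features, experimental_features)
  rf <- ranger::ranger(x = train[, pool, drop = FALSE], y = train[[target]],
                       num.trees = 40, max.depth = 10,
                       seed = derive_seed(seed, "featsel"),
                       num.threads = 1)
  pf <- function(X) stats::predict(rf, data = as.data.frame(X),
                                   num.threads = 1)$predictions
  sh <- shap_sampling(pf, train[, pool, drop = FALSE],
                      n_perm = n_perm, seed = derive_seed(seed, "shap"))
  score <- colMeans(abs(sh$attributions))
  at_score <- score[atomistic_features]
  # stable sort: descending score, ties in registry order
  ord <- order(-at_score, seq_along(at_score))
  ranking <- data.frame(feature = atomistic_features[ord],
                        mean_abs_shap = unname(at_score[ord]))
  top <- ranking$feature[seq_len(k)]
  structure(list(
    final_set = c(top, experimental_features),
    selected_atomistic = top,
    experimental = experimental_features,
    shap_ranking = ranking,
    k = k, seed = seed),
    class = "feature_selection")
}

#' @export
print.feature_selection <- function(x, ...) {
  cat("<feature_selection>", length(x$final_set), "features:",
      paste(x$final_set, collapse = ", "), "\n")
  invisible(x)
}
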