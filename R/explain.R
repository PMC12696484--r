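#' Global and local Shapley summary for a tuned model
#'
#' Wraps [shap_sampling()] around a `tuned_model`: returns the per-row
#' attribution matrix, the base value, and the global ranking table sorted
#' by descending mean absolute attribution.
#'
#' @param model a `tuned_model` (see [fit_final()]).
#' @param data rows to explain (must contain the model's features).
#' @param n_perm,max_background,seed forwarded to [shap_sampling()].
#' @return list with `global` (data.frame feature / mean_abs_shap),
#'   `local` (attribution matrix), `base_value`, `prediction`.
#' @export
shap_summary <- function(model, data, n_perm = 64, max_background = 20,
                         seed = 1L) {
  stopif(nrow(data) == 0L, "no rows to explain")
  X <- data[, model$features, drop = FALSE]
  sh <- shap_sampling(function(Z) {
    colnames(Z) <- model$features
    predict(model, as.data.frame(Z))
  }, X, n_perm = n_perm, max_background = max_background,
  seed = derive_seed(seed, "explain"))
  score <- colMeans(abs(sh$attributions))
  ord <- order(-score, seq_along(score))
  list(global = data.frame(feature = model$features[ord],
                           mean_abs_shap = unname(score[ord])),
       local = sh$attributions, base_value = sh$base_value,
       prediction = sh$prediction)
}

#' Permutation feature importance
#'
#' Shuffles one feature column at a time and records the degradation of a
#' metric (default MAE increase) over `n_repeats` shuffles.
#'
#' @param model a `tuned_model`.
#' @param data evaluation rows.
#' @param target response column in `data`.
#' @param metric `"mae"` or `"rmse"`.
#' @param n_repeats shuffles per feature (>= 1).
#' @param seed integer seed.
#' @return data.frame `feature`, `mean_drop`, `sd_drop`, sorted descending.
#' @export
permutation_importance <- function(model, data, target, metric = "mae",
                                   n_repeats = 5, seed = 1L) {
  stopif(n_repeats < 1, "n_repeats must be >= 1")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(derive_seed(seed, "explain"))
  y <- data[[target]]
  score <- function(pred) {
    if (metric == "mae") mean(abs(y - pred)) else sqrt(mean((y - pred)^2))
  }
  base <- score(predict(model, data))
  rows <- lapply(model$features, function(f) {
    drops <- vapply(seq_len(n_repeats), function(r) {
      shuffled <- data
      shuffled[[f]] <- sample(shuffled[[f]])
      score(predict(model, shuffled)) - base
    }, 0)
    data.frame(feature = f, mean_drop = mean(drops),
               sd_drop = stats::sd(drops))
  })
  out <- do.call(rbind, rows)
  out[order(-out$mean_drop), ]
}

#' Performance vs progressive feature addition
#'
#' Refits the model on the top-k prefixes of a feature ranking
#' (k = 1 ... all) and reports test R2 and RMSE per k. The curve need not
#' be monotone.
#'
#' @param train,test data.frames.
#' @param target response column.
#' @param ranked_features features in importance order.
#' @param algorithm_id,hyper model definition for the refits.
#' @param seed integer seed.
#' @return data.frame `k`, `feature_added`, `r2`, `rmse`.
#' @export
feature_addition_curve <- function(train, test, target, ranked_features,
                                   algorithm_id, hyper = list(), seed = 1L) {
  rows <- lapply(seq_along(ranked_features), function(k) {
    feats <- ranked_features[seq_len(k)]
    m <- fit_final(train, target, feats, algorithm_id = algorithm_id,
                   hyper = hyper, seed = seed)
    met <- regression_metrics(test[[target]], predict(m, test))
    data.frame(k = k, feature_added = ranked_features[k], r2 = met$r2,
               rmse = met$rmse)
  })
  do.call(rbind, rows)
}

#' Partial dependence and ICE curves
#'
#' PDP: mean model output over the data with `feature` substituted at each
#' grid value; ICE: the per-row curves whose mean the PDP is. Grids default
#' to the deciles of the feature's distribution in `data`. The `centred`
#' option subtracts each ICE curve's first value. With two features a 2-D
#' PDP surface is returned.
#'
#' @param model a `tuned_model`.
#' @param data rows to average over.
#' @param feature one feature name, or two for a 2-D surface.
#' @param grid optional explicit grid (vector, or list of two vectors).
#' @param grid_size grid resolution when deciles are used.
#' @param centred subtract each curve's first value (1-D only).
#' @return For 1-D: list with `grid`, `pdp`, `ice` (rows x grid matrix).
#'   For 2-D: list with `grid1`, `grid2`, `pdp` (matrix).
#' @export
pdp_ice <- function(model, data, feature, grid = NULL, grid_size = 10,
                    centred = FALSE) {
  stopif(!all(feature %in% model$features), "feature not in model: ",
         paste(setdiff(feature, model$features), collapse = ", "))
  make_grid <- function(f) {
    unique(unname(stats::quantile(data[[f]],
                                  probs = seq(0, 1,
                                              length.out = grid_size))))
  }
  if (length(feature) == 1L) {
    g <- grid %||% make_grid(feature)
    ice <- vapply(g, function(v) {
      d <- data
      d[[feature]] <- v
      predict(model, d)
    }, numeric(nrow(data)))
    if (is.null(dim(ice))) ice <- matrix(ice, nrow = nrow(data))
    if (centred) ice <- ice - ice[, 1]
    list(grid = g, pdp = colMeans(ice), ice = ice)
  } else if (length(feature) == 2L) {
    g1 <- if (is.list(grid)) grid[[1]] else make_grid(feature[1])
    g2 <- if (is.list(grid)) grid[[2]] else make_grid(feature[2])
    pdp <- matrix(NA_real_, length(g1), length(g2))
    for (i in seq_along(g1)) for (j in seq_along(g2)) {
      d <- data
      d[[feature[1]]] <- g1[i]; d[[feature[2]]] <- g2[j]
      pdp[i, j] <- mean(predict(model, d))
    }
    list(grid1 = g1, grid2 = g2, pdp = pdp)
  } else stop("feature must name one or two columns")
}

#' Waterfall payload for a single prediction
#'
#' Serialisable per-sample explanation: base value, signed per-feature
#' contributions sorted by absolute magnitude, and the final prediction
#' (base + contributions, exactly).
#'
#' @param model a `tuned_model`.
#' @param row a single-row data.frame.
#' @param background background rows for the attribution (e.g. the
#'   training features).
#' @param n_perm,seed forwarded to [shap_sampling()].
#' @return list with `base_value`, `contributions` (named, sorted),
#'   `prediction`.
#' @export
waterfall_export <- function(model, row, background = NULL, n_perm = 64,
                             seed = 1L) {
  stopif(nrow(row) != 1L, "waterfall explains exactly one row")
  X <- row[, model$features, drop = FALSE]
  bg <- if (is.null(background)) NULL else
    background[, model$features, drop = FALSE]
  sh <- shap_sampling(function(Z) {
    colnames(Z) <- model$features
    predict(model, as.data.frame(Z))
  }, X, background = bg, n_perm = n_perm,
  seed = derive_seed(seed, "explain"))
  contrib <- sh$attributions[1, ]
  contrib <- contrib[order(-abs(contrib))]
  list(base_value = sh$base_value, contributions = contrib,
       prediction = unname(sh$prediction[1]))
}
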