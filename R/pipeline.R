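#' Pipeline run configuration
#'
#' Collects every knob of the end-to-end workflow. `approach` selects the
#' feature strategy: `"evidence"` models the experimental/exposure columns
#' only (no CIFs, no descriptors), `"atomistic"` augments them with the
#' 57-descriptor vector and runs feature selection down to the default 13
#' features.
#'
#' @param approach `"atomistic"` (default) or `"evidence"`.
#' @param cif_dir directory of CIF files (one per phase); `NULL` uses the
#'   built-in synthetic toy cells.
#' @param dataset_csv viability CSV path; `NULL` simulates the default
#'   scenario.
#' @param out_dir output directory for artifacts; `NULL` writes nothing.
#' @param seed master seed; every stage derives its own seed from it.
#' @param test_frac,shell_depth,k_top,n_draws,cv_k,apd_Z,bootstrap_B,
#'   scramble_rounds,shap_n_perm stage overrides (defaults match the
#'   package-wide defaults).
#' @param specs model pool, see [default_model_specs()].
#' @param scenario simulation scenario when no CSV is given.
#' @return A `run_config` list.
#' @export
run_config <- function(approach = c("atomistic", "evidence"),
                       cif_dir = NULL, dataset_csv = NULL, out_dir = NULL,
                       seed = 1L, test_frac = 0.30, shell_depth = 4,
                       k_top = 8, n_draws = 25, cv_k = 5, apd_Z = 0.5,
                       bootstrap_B = 200, scramble_rounds = 5,
                       shap_n_perm = 64, specs = default_model_specs(),
                       scenario = NULL) {
  approach <- match.arg(approach)
  structure(as.list(environment()), class = "run_config")
}

experimental_feature_sets <- function() {
  list(
    evidence = c("core_diameter", "size_sd", "shell_material",
                 "shell_thickness", "coating_group", "concentration",
                 "cell_line", "organism", "health_status", "phase_code"),
    atomistic_five = c("core_diameter", "coating_group", "shell_material",
                       "shell_thickness", "concentration")
  )
}

#' Run the full modelling workflow
#'
#' Executes build -> descriptors (atomistic approach only) -> curate ->
#' split -> select -> nested CV -> final fit -> validation (test metrics,
#' leave-one-out Q2, Golbraikh-Tropsha, Y-scrambling, bootstrap) -> APD
#' (Euclidean and Gower) -> explanation (Shapley, permutation importance,
#' feature-addition curve, partial dependence), logging each stage. All
#' randomness derives from `config$seed`; the same config reproduces the
#' same artifacts.
#'
#' @param config a [run_config()].
#' @param quiet suppress stage messages.
#' @return A `pipeline_result` list of all stage artifacts.
#' @export
run_pipeline <- function(config = run_config(), quiet = FALSE) {
  say <- function(...) if (!quiet) message("[", format(Sys.time(), "%H:%M:%S"),
                                           "] ", ...)
  seed <- config$seed
  stage <- function(name, expr) {
    say("stage: ", name)
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  # ---- inputs -----------------------------------------------------------
  table <- stage("curate", {
    if (is.null(config$dataset_csv)) {
      sc <- config$scenario %||% sim_scenario(seed = seed)
      simulate_viability(sc)
    } else read_viability_csv(config$dataset_csv)
  })

  cells <- NULL; desc_tab <- NULL
  if (config$approach == "atomistic") {
    cells <- stage("build", {
      if (is.null(config$cif_dir)) toy_unit_cells() else {
        files <- list.files(config$cif_dir, "\\.cif$", full.names = TRUE)
        stopif(length(files) == 0L, "no CIF files in ", config$cif_dir)
        cl <- lapply(files, parse_cif)
        stats::setNames(cl, vapply(cl, `[[`, "", "phase_id"))
      }
    })
    desc_tab <- stage("descriptors", {
      parts <- unique(table[, c("phase", "core_diameter")])
      names(parts) <- c("phase", "diameter_nm")
      descriptor_table(cells, parts, shell_depth = config$shell_depth)
    })
    table <- stage("join", join_descriptors(table, desc_tab))
  }

  # ---- split & encode ---------------------------------------------------
  split <- stage("split", stratified_split(table, config$test_frac,
                                           seed = derive_seed(seed, "split")))
  enc <- stage("encode", {
    enc <- fit_encoding(table[split$train, , drop = FALSE])
    enc
  })
  encoded <- encode_records(table, enc)
  train <- encoded[split$train, , drop = FALSE]
  test <- encoded[split$test, , drop = FALSE]

  # ---- features ---------------------------------------------------------
  fsets <- experimental_feature_sets()
  selection <- NULL; filt <- NULL
  features <- if (config$approach == "evidence") {
    fsets$evidence
  } else {
    stage("select", {
      ids <- descriptor_registry()$id
      filt <- variance_correlation_filter(train, ids)
      selection <- shap_rank_select(
        train, "viability", filt$kept,
        experimental_features = fsets$atomistic_five,
        k = config$k_top, seed = seed)
      selection$final_set
    })
  }

  # ---- model development ------------------------------------------------
  cv <- stage("nested_cv",
              nested_cv(train, "viability", features, config$specs,
                        k = config$cv_k, n_draws = config$n_draws,
                        seed = seed))
  model <- stage("fit_final",
                 fit_final(train, "viability", features, cv, seed = seed))
  winner_hyper <- cv$results[[cv$winner]]$hyper

  # ---- validation -------------------------------------------------------
  validation <- stage("validate", {
    pred_test <- predict(model, test)
    pred_train <- predict(model, train)
    q2 <- loo_q2(train, "viability", features, model$algorithm_id,
                 winner_hyper, seed = seed)
    list(
      test = regression_metrics(test$viability, pred_test,
                                p = length(features)),
      train = regression_metrics(train$viability, pred_train,
                                 p = length(features)),
      q2_loo = q2,
      gt = golbraikh_tropsha(test$viability, pred_test, q2_loo = q2),
      scramble = y_scramble(train, test, "viability", features,
                            model$algorithm_id, winner_hyper,
                            n_rounds = config$scramble_rounds, seed = seed),
      bootstrap = bootstrap_ci(train, "viability", features,
                               model$algorithm_id, winner_hyper,
                               B = config$bootstrap_B, seed = seed),
      predictions = list(test = pred_test, train = pred_train)
    )
  })

  # ---- explanation (needed before APD for the Gower weights) ------------
  explanation <- stage("explain", {
    shap <- shap_summary(model, train, n_perm = config$shap_n_perm,
                         seed = seed)
    perm <- permutation_importance(model, test, "viability", seed = seed)
    add_curve <- feature_addition_curve(
      train, test, "viability",
      shap$global$feature, model$algorithm_id, winner_hyper, seed = seed)
    pdp_conc <- if ("concentration" %in% features)
      pdp_ice(model, train, "concentration", centred = TRUE) else NULL
    pdp_2d <- if (all(c("concentration", "core_diameter") %in% features))
      pdp_ice(model, train, c("concentration", "core_diameter")) else NULL
    wf <- waterfall_export(model, test[1, , drop = FALSE],
                           background = train, seed = seed)
    list(shap = shap, permutation = perm, addition_curve = add_curve,
         pdp_concentration = pdp_conc, pdp_2d = pdp_2d, waterfall = wf)
  })

  # ---- applicability domain --------------------------------------------
  apd <- stage("apd", {
    categorical_cols <- intersect(c("coating_group", "shell_material"),
                                  features)
    numeric_cols <- setdiff(features, categorical_cols)
    sc <- suppressWarnings(fit_scaler(train[, numeric_cols, drop = FALSE]))
    train_scaled <- as.data.frame(scale_apply(sc, train))
    eu <- fit_apd(train_scaled, "euclidean", Z = config$apd_Z)
    w <- explanation$shap$global
    weights <- w$mean_abs_shap[match(features, w$feature)]
    if (all(weights == 0)) weights <- rep(1, length(features))
    gw <- fit_apd(train[, features, drop = FALSE], "gower",
                  Z = config$apd_Z, weights = weights,
                  categorical = features %in% categorical_cols)
    test_eu <- in_domain(as.data.frame(scale_apply(sc, test)), eu)
    test_gw <- in_domain(test[, features, drop = FALSE], gw)
    list(euclidean = eu, gower = gw, scaler = sc,
         test_reliability = data.frame(
           euclidean = test_eu$reliable, gower = test_gw$reliable))
  })

  result <- structure(list(
    config = config, table = table, split = split, encoding = enc,
    descriptors = desc_tab, filter = filt, selection = selection,
    features = features, cv = cv, model = model,
    validation = validation, apd = apd, explanation = explanation
  ), class = "pipeline_result")

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(desc_tab))
      write_descriptor_csv(desc_tab,
                           file.path(config$out_dir, "descriptors.csv"))
    write_encoding_json(enc, file.path(config$out_dir, "encoding.json"))
    writeLines(generate_report(result),
               file.path(config$out_dir, "report.md"))
    utils::write.csv(
      data.frame(row = split$test, observed = test$viability,
                 predicted = validation$predictions$test,
                 apd$test_reliability),
      file.path(config$out_dir, "test_predictions.csv"), row.names = FALSE)
  }
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>", x$config$approach, "approach;",
      nrow(x$table), "rows;", length(x$features), "features\n")
  cat("  winner:", x$model$algorithm_id,
      sprintf("(MAE_cv %.4f)\n", x$cv$mae_cv[x$cv$winner]))
  v <- x$validation
  cat(sprintf("  test R2 %.3f, MAE %.3f | train R2 %.3f | Q2_loo %.3f\n",
              v$test$r2, v$test$mae, v$train$r2, v$q2_loo))
  cat("  Golbraikh-Tropsha:", if (v$gt$pass) "PASS" else "FAIL",
      "| scrambling:", v$scramble$verdict, "\n")
  cat(sprintf("  APD thresholds: euclidean %.4f, gower %.4f\n",
              x$apd$euclidean$threshold, x$apd$gower$threshold))
  invisible(x)
}
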