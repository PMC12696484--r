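#' QMRF-style model report
#'
#' Renders a structured markdown document covering the five OECD QSAR
#' principles: (1) the modelled endpoint, (2) the algorithm, (3) the
#' applicability domain, (4) goodness-of-fit, robustness and predictivity
#' (test/train metrics, Q2_loo, Golbraikh-Tropsha flags, Y-scrambling,
#' bootstrap intervals), and (5) mechanistic interpretation of the
#' selected features. A machine-readable key-value block closes the
#' document. Artifacts missing from the result are listed as
#' "not computed"; regenerating from the same result is idempotent.
#'
#' @param result a `pipeline_result` from [run_pipeline()].
#' @return character vector of markdown lines.
#' @export
generate_report <- function(result) {
  v <- result$validation
  fmt <- function(x, d = 4) {
    if (is.null(x) || length(x) == 0 || is.na(x)) "not computed"
    else formatC(x, digits = d, format = "f")
  }
  gt <- v$gt
  lines <- c(
    "# QSTR model report",
    "",
    "## 1. Defined endpoint",
    paste0("Cell viability (fraction of untreated control) of immortalised ",
           "cell lines after 24 h exposure to spherical iron carbide ",
           "nanoparticles; treatments with viability < 0.70 are labelled ",
           "cytotoxic."),
    sprintf("Dataset: %d treatments, %d experiments, %.1f%% cytotoxic.",
            nrow(result$table),
            length(unique(result$table$experiment_id)),
            100 * mean(result$table$viability < 0.70)),
    "",
    "## 2. Unambiguous algorithm",
    sprintf("Approach: %s. Winning algorithm: %s (MAE_cv = %s).",
            result$config$approach, result$model$algorithm_id,
            fmt(result$cv$mae_cv[result$cv$winner])),
    sprintf("Hyperparameters: %s.",
            paste(names(result$model$hyper),
                  vapply(result$model$hyper, function(h) format(h, digits = 4), ""),
                  sep = " = ", collapse = ", ")),
    sprintf("Features (%d): %s.", length(result$features),
            paste(result$features, collapse = ", ")),
    if (!is.null(result$cv$skipped) && length(result$cv$skipped))
      sprintf("Algorithms skipped (backend unavailable): %s.",
              paste(result$cv$skipped, collapse = ", ")) else NULL,
    "",
    "## 3. Applicability domain",
    sprintf(paste0("Distance-to-nearest-training-neighbour thresholds ",
                   "`<d> + Z sigma` (Z = %.2f):"), result$config$apd_Z),
    sprintf("- Euclidean (z-scaled numeric features): threshold = %s",
            fmt(result$apd$euclidean$threshold)),
    sprintf("- Weighted Gower (mixed types, SHAP weights): threshold = %s",
            fmt(result$apd$gower$threshold)),
    sprintf("Test rows inside the domain: %d/%d (Euclidean), %d/%d (Gower).",
            sum(result$apd$test_reliability$euclidean),
            nrow(result$apd$test_reliability),
            sum(result$apd$test_reliability$gower),
            nrow(result$apd$test_reliability)),
    "",
    "## 4. Goodness-of-fit, robustness, predictivity",
    "",
    "| metric | test | training |",
    "|---|---|---|",
    sprintf("| R2 | %s | %s |", fmt(v$test$r2, 3), fmt(v$train$r2, 3)),
    sprintf("| adjusted R2 | %s | %s |", fmt(v$test$adj_r2, 3),
            fmt(v$train$adj_r2, 3)),
    sprintf("| MAE | %s | %s |", fmt(v$test$mae), fmt(v$train$mae)),
    sprintf("| MSE | %s | %s |", fmt(v$test$mse), fmt(v$train$mse)),
    sprintf("| RMSE | %s | %s |", fmt(v$test$rmse), fmt(v$train$rmse)),
    "",
    "Golbraikh-Tropsha acceptability:",
    sprintf("- r2 = %s (> 0.6: %s)", fmt(gt$r2, 3),
            ifelse(gt$flags$r2_gt_0.6, "pass", "fail")),
    sprintf("- Q2_loo = %s (> 0.5: %s)", fmt(gt$q2_loo, 3),
            ifelse(gt$flags$q2_loo_gt_0.5, "pass", "fail")),
    sprintf("- (r2 - r02)/r2 = %s; (r2 - r0'2)/r2 = %s (one < 0.1: %s)",
            fmt(gt$ratio, 3), fmt(gt$ratio_prime, 3),
            ifelse(gt$flags$ratio_lt_0.1, "pass", "fail")),
    sprintf("- k = %s, k' = %s (one in (0.85, 1.15): %s)",
            fmt(gt$k, 3), fmt(gt$k_prime, 3),
            ifelse(gt$flags$slope_in_window, "pass", "fail")),
    sprintf("- overall: %s", ifelse(gt$pass, "PASS", "FAIL")),
    "",
    sprintf("Y-scrambling (%d rounds): true test R2 = %s vs scrambled %s; %s.",
            length(v$scramble$scrambled_r2), fmt(v$scramble$true$r2, 3),
            paste(formatC(v$scramble$scrambled_r2, digits = 3,
                          format = "f"), collapse = ", "),
            v$scramble$verdict),
    sprintf(paste0("Bootstrap (B = %d, out-of-bag, %d%% level): ",
                   "MAE [%s, %s], R2 [%s, %s]."),
            v$bootstrap$B, round(100 * v$bootstrap$level),
            fmt(v$bootstrap$ci_mae[1]), fmt(v$bootstrap$ci_mae[2]),
            fmt(v$bootstrap$ci_r2[1], 3), fmt(v$bootstrap$ci_r2[2], 3)),
    "",
    "## 5. Mechanistic interpretation",
    "Global feature importance (mean |SHAP|, descending):",
    sprintf("- %s: %s", result$explanation$shap$global$feature,
            formatC(result$explanation$shap$global$mean_abs_shap,
                    digits = 4, format = "f")),
    "",
    "Positive attributions push predicted viability up (non-cytotoxic);",
    "negative attributions push it toward cytotoxicity.",
    "",
    "## Machine-readable summary",
    "```",
    sprintf("approach=%s", result$config$approach),
    sprintf("winner=%s", result$model$algorithm_id),
    sprintf("n_features=%d", length(result$features)),
    sprintf("mae_cv=%s", fmt(result$cv$mae_cv[result$cv$winner])),
    sprintf("test_r2=%s", fmt(v$test$r2)),
    sprintf("test_mae=%s", fmt(v$test$mae)),
    sprintf("train_r2=%s", fmt(v$train$r2)),
    sprintf("q2_loo=%s", fmt(v$q2_loo)),
    sprintf("gt_pass=%s", gt$pass),
    sprintf("apd_threshold_euclidean=%s", fmt(result$apd$euclidean$threshold)),
    sprintf("apd_threshold_gower=%s", fmt(result$apd$gower$threshold)),
    sprintf("seed=%d", result$config$seed),
    "```"
  )
  lines[!vapply(lines, is.null, TRUE)]
}
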