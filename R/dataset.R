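#' Read a viability dataset CSV
#'
#' One row per treatment. Required columns: `experiment_id`, `phase`,
#' `core_diameter` (nm), `size_sd` (nm), `shell_material`,
#' `shell_thickness` (nm), `coating`, `concentration` (ug/mL),
#' `cell_line`, `organism`, `health_status`, `viability`.
#' Viability is stored as a fraction of the untreated control; columns
#' reported in percent (values > 2) are divided by 100 on read. Zeta
#' potential and hydrodynamic size columns are accepted but dropped.
#'
#' @param path CSV file path.
#' @return data.frame of viability records.
#' @export
read_viability_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("experiment_id", "phase", "core_diameter", "size_sd",
                "shell_material", "shell_thickness", "coating",
                "concentration", "cell_line", "organism", "health_status",
                "viability")
  miss <- setdiff(required, names(df))
  stopif(length(miss) > 0, "viability CSV missing column(s): ",
         paste(miss, collapse = ", "))
  drop <- intersect(c("zeta_potential", "hydrodynamic_size"), names(df))
  if (length(drop)) df <- df[, setdiff(names(df), drop)]
  if (any(df$viability > 2, na.rm = TRUE)) df$viability <- df$viability / 100
  stopif(any(df$viability < 0, na.rm = TRUE), "negative viability values")
  stopif(any(df$concentration <= 0, na.rm = TRUE),
         "concentrations must be positive")
  df
}

#' Cytotoxicity label from a viability fraction
#'
#' ISO-style rule: a treatment is cytotoxic iff viability drops strictly
#' below 70 % of the control.
#'
#' @param viability numeric fraction(s) of control, `>= 0`.
#' @return character vector in `{"cytotoxic", "non-cytotoxic"}`.
#' @export
label_cytotoxicity <- function(viability) {
  stopif(any(viability < 0), "viability must be non-negative")
  ifelse(viability < 0.70, "cytotoxic", "non-cytotoxic")
}

#' Default coating-group keyword table
#'
#' Maps free-text surface modifiers onto functional groups. Matched against
#' the lower-cased coating string; the first matching group wins, no match
#' falls into `"other"`, and an empty / "none" coating is `"bare"`.
#' @export
default_coating_keywords <- function() {
  list(
    bare = c("^$", "^none$", "^bare$", "uncoated", "^-$"),
    `polymer-based` = c("peg", "polyethylene glycol", "poly", "pluronic",
                        "pvp", "pva", "dextran", "chitosan", "acrylic"),
    `protein-based` = c("albumin", "bsa", "protein", "transferrin",
                        "antibody", "peptide", "collagen", "gelatin")
  )
}

coating_group_of <- function(coating, keywords = default_coating_keywords()) {
  x <- tolower(trimws(coating))
  vapply(x, function(s) {
    for (grp in names(keywords)) {
      if (any(vapply(keywords[[grp]], function(p) grepl(p, s), TRUE)))
        return(grp)
    }
    "other"
  }, "", USE.NAMES = FALSE)
}

#' Fit the categorical encoding dictionary on training records
#'
#' Ordinal and binary encodings: coating group
#' `{bare = 0, polymer-based = 1, protein-based = 2, other = 3}`;
#' shell material ordinal by descending training frequency (most frequent
#' = 0); health status binary `{normal = 0, cancer = 1}`; organism binary
#' by descending frequency; cell line ordinal by descending frequency;
#' phase ordinal by carbon stoichiometry order `Fe2C < Fe3C < Fe5C2` (or
#' training frequency for other labels).
#'
#' @param records training data.frame of viability records.
#' @param keywords coating keyword table, see [default_coating_keywords()].
#' @return An `encoding_dictionary` object; persist with
#'   [write_encoding_json()].
#' @export
fit_encoding <- function(records, keywords = default_coating_keywords()) {
  by_freq <- function(x) {
    lv <- names(sort(table(x), decreasing = TRUE))
    stats::setNames(seq_along(lv) - 1L, lv)
  }
  phase_known <- c(Fe2C = 0L, Fe3C = 1L, Fe5C2 = 2L)
  phases <- unique(records$phase)
  phase_map <- if (all(phases %in% names(phase_known)))
    phase_known[intersect(names(phase_known), phases)] else by_freq(records$phase)
  hs <- tolower(records$health_status)
  structure(list(
    coating_group = c(bare = 0L, `polymer-based` = 1L, `protein-based` = 2L,
                      other = 3L),
    keywords = keywords,
    shell_material = by_freq(tolower(records$shell_material)),
    health_status = c(normal = 0L, cancer = 1L),
    organism = by_freq(tolower(records$organism)),
    cell_line = by_freq(records$cell_line),
    phase = phase_map
  ), class = "encoding_dictionary")
}

lookup_encoded <- function(x, map, what) {
  idx <- match(x, names(map))
  if (anyNA(idx)) {
    warning("unseen ", what, " value(s) at encode time: ",
            paste(unique(x[is.na(idx)]), collapse = ", "),
            "; mapped to the most frequent level and flagged",
            call. = FALSE)
  }
  list(value = ifelse(is.na(idx), as.integer(map[1]),
                      as.integer(map[idx])),
       flagged = is.na(idx))
}

#' Encode viability records numerically
#'
#' Applies a fitted [fit_encoding()] dictionary. Unseen categories map to
#' the most frequent training level with a warning and are marked in the
#' `encoding_flagged` column (relevant for applicability-domain gating).
#'
#' @param records data.frame of viability records.
#' @param enc an `encoding_dictionary`.
#' @return data.frame with numeric columns `coating_group`,
#'   `shell_material`, `health_status`, `organism`, `cell_line`, `phase_code`
#'   added alongside the numeric exposure columns, plus `cytotoxic` labels
#'   and `encoding_flagged`.
#' @export
encode_records <- function(records, enc) {
  stopif(!inherits(enc, "encoding_dictionary"),
         "enc must come from fit_encoding()")
  grp <- coating_group_of(records$coating, enc$keywords)
  out <- records
  flagged <- rep(FALSE, nrow(records))
  out$coating_group <- as.integer(enc$coating_group[grp])
  for (col in c("shell_material", "organism")) {
    r <- lookup_encoded(tolower(records[[col]]), enc[[col]], col)
    out[[col]] <- r$value; flagged <- flagged | r$flagged
  }
  hs <- lookup_encoded(tolower(records$health_status), enc$health_status,
                       "health_status")
  out$health_status <- hs$value; flagged <- flagged | hs$flagged
  cl <- lookup_encoded(records$cell_line, enc$cell_line, "cell_line")
  out$cell_line <- cl$value; flagged <- flagged | cl$flagged
  ph <- lookup_encoded(records$phase, enc$phase, "phase")
  out$phase_code <- ph$value; flagged <- flagged | ph$flagged
  out$cytotoxic <- label_cytotoxicity(records$viability)
  out$encoding_flagged <- flagged
  out
}

#' @rdname fit_encoding
#' @param enc an `encoding_dictionary`.
#' @param path JSON output path.
#' @export
write_encoding_json <- function(enc, path) {
  jsonlite::write_json(lapply(unclass(enc)[setdiff(names(enc), "keywords")],
                              as.list),
                       path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Constrained stratified 70:30 split
#'
#' Two-stage draw: (1) one uniformly chosen row of every experiment with at
#' least two rows goes to the test set, so every chemistry is represented
#' in the hold-out; (2) the remaining test quota is filled by sampling
#' stratified on the binary cytotoxicity label, keeping the label
#' proportions of train and test within five percentage points of the full
#' table. Single-row experiments stay in training with a warning.
#'
#' @param table encoded data.frame with `experiment_id` and `cytotoxic`
#'   columns.
#' @param test_frac test fraction, in (0, 1); default 0.30.
#' @param seed integer seed; the same seed reproduces the same split.
#' @return A `split_index` list: `train`, `test` (integer row indices),
#'   `seed`, `strata` (the label vector used).
#' @export
stratified_split <- function(table, test_frac = 0.30, seed = 1L) {
  stopif(test_frac <= 0 || test_frac >= 1, "test_frac must be in (0, 1)")
  n <- nrow(table)
  label <- table$cytotoxic %||% label_cytotoxicity(table$viability)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  n_test <- round(test_frac * n)
  exps <- split(seq_len(n), table$experiment_id)
  singles <- vapply(exps, length, 1L) == 1L
  if (any(singles))
    warning(sum(singles), " single-row experiment(s) kept in training; ",
            "the one-per-experiment hold-out rule cannot apply to them",
            call. = FALSE)
  test <- vapply(exps[!singles], function(ix) ix[sample.int(length(ix), 1L)],
                 1L)
  test <- unname(test)
  if (length(test) > n_test)
    warning("more experiments than the test quota; test fraction exceeds ",
            test_frac, call. = FALSE)

  remaining <- setdiff(seq_len(n), test)
  quota <- n_test - length(test)
  tb <- base::table(label)
  p_full <- stats::setNames(as.numeric(tb) / n, names(tb))
  want <- round(p_full * n_test)
  if (quota > 0) {
    # fill by label so test matches the full-table label proportions
    have <- base::table(factor(label[test], names(p_full)))
    need <- stats::setNames(pmax(0, want - as.numeric(have)), names(p_full))
    extra <- integer()
    for (lv in names(p_full)) {
      pool <- remaining[label[remaining] == lv]
      k <- min(need[[lv]], length(pool), quota - length(extra))
      if (k > 0) extra <- c(extra, pool[sample.int(length(pool), k)])
    }
    short <- quota - length(extra)
    if (short > 0) {
      pool <- setdiff(remaining, extra)
      extra <- c(extra, pool[sample.int(length(pool), short)])
    }
    test <- c(test, extra)
  }
  train <- setdiff(seq_len(n), test)

  # repair pass: the per-experiment draw can overfill one stratum; swap
  # test rows of the over-represented label for train rows of the other,
  # never removing an experiment's only test representative
  for (rep_step in seq_len(n)) {
    have <- base::table(factor(label[test], names(p_full)))
    over <- names(p_full)[which(as.numeric(have) - want >= 1)]
    under <- names(p_full)[which(as.numeric(have) - want <= -1)]
    if (length(over) == 0L || length(under) == 0L) break
    exp_test_counts <- base::table(table$experiment_id[test])
    removable <- test[label[test] == over[1] &
                        exp_test_counts[table$experiment_id[test]] >= 2]
    addable <- train[label[train] == under[1]]
    if (length(removable) == 0L || length(addable) == 0L) break
    out_row <- removable[sample.int(length(removable), 1L)]
    in_row <- addable[sample.int(length(addable), 1L)]
    test <- c(setdiff(test, out_row), in_row)
    train <- c(setdiff(train, in_row), out_row)
  }

  p_all <- mean(label == "cytotoxic")
  for (part in list(train = train, test = test)) {
    if (abs(mean(label[part] == "cytotoxic") - p_all) > 0.05)
      warning("label proportion drifted more than 5 points in a subset",
              call. = FALSE)
  }
  structure(list(train = sort(train), test = sort(test), seed = seed,
                 strata = label),
            class = "split_index")
}

#' @export
print.split_index <- function(x, ...) {
  cat("<split_index>", length(x$train), "train /", length(x$test),
      "test rows (seed", x$seed, ")\n")
  invisible(x)
}

#' Z-score scaler fitted on training rows
#'
#' Centers and scales with the *training* mean and population standard
#' deviation only (the convention is population sd, switchable with
#' `population = FALSE`); constant columns pass through unscaled with a
#' warning.
#'
#' @param train data.frame or matrix of numeric training features.
#' @param population use the population (divide by n) standard deviation.
#' @return A `feature_scaler`.
#' @export
fit_scaler <- function(train, population = TRUE) {
  train <- as.matrix(train)
  mu <- colMeans(train)
  sdv <- apply(train, 2, function(x) {
    s <- stats::sd(x)
    if (population) s * sqrt((length(x) - 1) / length(x)) else s
  })
  const <- !is.finite(sdv) | sdv == 0
  if (any(const))
    warning("constant column(s) pass through unscaled: ",
            paste(colnames(train)[const], collapse = ", "), call. = FALSE)
  sdv[const] <- 1
  mu[const] <- 0
  structure(list(mean = mu, sd = sdv, constant = const,
                 population = population),
            class = "feature_scaler")
}

#' @rdname fit_scaler
#' @param scaler a fitted `feature_scaler`.
#' @param x new data with the training columns.
#' @export
scale_apply <- function(scaler, x) {
  cols <- names(scaler$mean)
  if (is.data.frame(x)) {
    stopif(!all(cols %in% names(x)), "missing feature column(s): ",
           paste(setdiff(cols, names(x)), collapse = ", "))
    x <- as.matrix(x[, cols, drop = FALSE])
  } else {
    x <- as.matrix(x)
    stopif(!all(cols %in% colnames(x)), "missing feature column(s): ",
           paste(setdiff(cols, colnames(x)), collapse = ", "))
    x <- x[, cols, drop = FALSE]
  }
  sweep(sweep(x, 2, scaler$mean), 2, scaler$sd, "/")
}

#' @rdname fit_scaler
#' @export
scale_invert <- function(scaler, x) {
  x <- as.matrix(x)
  sweep(sweep(x, 2, scaler$sd, "*"), 2, scaler$mean, "+")
}

#' Join atomistic descriptors onto a viability table
#'
#' Matches every `(phase, core_diameter)` pair to its descriptor row by
#' nearest diameter within a 0.1 nm tolerance; the row count never changes.
#' Unmatched or ambiguous particles are errors listing the offending pairs.
#'
#' @param table viability data.frame with `phase` and `core_diameter` (nm).
#' @param descriptors a [descriptor_table()] data.frame (or a CSV path).
#' @param tol diameter matching tolerance (nm).
#' @return `table` with `D1`...`D57` columns appended.
#' @export
join_descriptors <- function(table, descriptors, tol = 0.1) {
  if (is.character(descriptors))
    descriptors <- utils::read.csv(descriptors, stringsAsFactors = FALSE)
  stopif(nrow(descriptors) == 0L, "empty descriptor table")
  ids <- grep("^D[0-9]+$", names(descriptors), value = TRUE)
  missing <- character(); amb <- character()
  rows <- integer(nrow(table))
  for (k in seq_len(nrow(table))) {
    cand <- which(descriptors$phase == table$phase[k] &
                    abs(descriptors$diameter_nm - table$core_diameter[k]) <= tol)
    key <- paste0(table$phase[k], "@", table$core_diameter[k], "nm")
    if (length(cand) == 0L) { missing <- c(missing, key); next }
    d <- abs(descriptors$diameter_nm[cand] - table$core_diameter[k])
    best <- cand[d == min(d)]
    if (length(best) > 1L) { amb <- c(amb, key); next }
    rows[k] <- best
  }
  stopif(length(missing) > 0, "no descriptor row for particle(s): ",
         paste(unique(missing), collapse = ", "))
  stopif(length(amb) > 0, "ambiguous duplicate descriptor rows for: ",
         paste(unique(amb), collapse = ", "))
  cbind(table, descriptors[rows, ids, drop = FALSE], row.names = NULL)
}
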