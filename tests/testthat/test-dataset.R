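make_records <- function() {
  simulate_viability(small_scenario())
}

test_that("cytotoxicity labelling applies the strict 70 % rule", {
  expect_equal(label_cytotoxicity(c(0.699, 0.70, 1.05, 0)),
               c("cytotoxic", "non-cytotoxic", "non-cytotoxic", "cytotoxic"))
  expect_error(label_cytotoxicity(-0.1), "non-negative")
  # brute-force equivalence on a random table
  set.seed(5)
  v <- runif(200, 0, 1.3)
  expect_equal(label_cytotoxicity(v) == "cytotoxic", v < 0.7)
})

test_that("coating free text maps onto the functional groups", {
  expect_equal(coating_group_of("PEG"), "polymer-based")
  expect_equal(coating_group_of("polyethylene glycol"), "polymer-based")
  expect_equal(coating_group_of("none"), "bare")
  expect_equal(coating_group_of(""), "bare")
  expect_equal(coating_group_of("bovine serum albumin"), "protein-based")
  expect_equal(coating_group_of("doxorubicin"), "other")
})

test_that("encoding is ordinal/binary with a persistable dictionary", {
  rec <- make_records()
  enc <- fit_encoding(rec)
  out <- encode_records(rec, enc)
  expect_true(all(out$coating_group %in% 0:3))
  expect_true(all(out$health_status %in% 0:1))
  expect_true(all(out$organism %in% 0:1))
  # shell material ordinal by descending training frequency
  freq <- sort(table(tolower(rec$shell_material)), decreasing = TRUE)
  expect_equal(names(enc$shell_material)[1], names(freq)[1])
  expect_equal(unname(enc$shell_material[names(freq)[1]]), 0L)
  # persistence round trip
  f <- tempfile(fileext = ".json")
  write_encoding_json(enc, f)
  back <- jsonlite::read_json(f)
  expect_equal(unlist(back$coating_group),
               c(bare = 0, `polymer-based` = 1, `protein-based` = 2,
                 other = 3))
  # unseen category falls back with a warning and a flag
  odd <- rec[1, ]
  odd$shell_material <- "unobtainium"
  expect_warning(enc2 <- encode_records(odd, enc), "unseen")
  expect_true(enc2$encoding_flagged[1])
})

test_that("viability CSV round trip converts percentages and drops omitted
           columns", {
  rec <- make_records()
  f <- tempfile(fileext = ".csv")
  pct <- rec
  pct$viability <- pct$viability * 100
  pct$zeta_potential <- rnorm(nrow(pct))
  write_viability_csv(pct, f)
  back <- read_viability_csv(f)
  expect_equal(back$viability, rec$viability, tolerance = 1e-9)
  expect_false("zeta_potential" %in% names(back))
  # missing required column errors by name
  bad <- rec[, setdiff(names(rec), "concentration")]
  write_viability_csv(bad, f)
  expect_error(read_viability_csv(f), "concentration")
})

test_that("the constrained stratified split honours its contract on many
           random tables", {
  set.seed(99)
  for (rep in 1:100) {
    n_exp <- sample(5:12, 1)
    rows_per <- sample(4:10, 1)
    tab <- data.frame(
      experiment_id = rep(sprintf("E%02d", seq_len(n_exp)), each = rows_per),
      viability = runif(n_exp * rows_per, 0.2, 1.2))
    # the split itself warns when granularity forces a drift > 5 points on
    # very small tables; the assertions below allow exactly that slack
    sp <- suppressWarnings(stratified_split(tab, 0.3, seed = rep))
    n <- nrow(tab)
    # partition
    expect_identical(sort(c(sp$train, sp$test)), seq_len(n))
    expect_length(intersect(sp$train, sp$test), 0L)
    # every experiment appears in test
    expect_setequal(unique(tab$experiment_id[sp$test]),
                    unique(tab$experiment_id))
    # fraction within one row per stratum of the quota
    expect_lte(abs(length(sp$test) - round(0.3 * n)), 2L)
    # label proportions within 5 points, allowing one-row granularity on
    # small subsets
    lab <- tab$viability < 0.7
    if (sum(lab) >= 5) {
      expect_lte(abs(mean(lab[sp$test]) - mean(lab)),
                 0.051 + 1 / length(sp$test))
      expect_lte(abs(mean(lab[sp$train]) - mean(lab)),
                 0.051 + 1 / length(sp$train))
    }
  }
})

test_that("splits are deterministic and degenerate cases behave", {
  tab <- data.frame(experiment_id = rep("only", 40),
                    viability = runif(40, 0.3, 1.1))
  s1 <- stratified_split(tab, 0.3, seed = 4)
  s2 <- stratified_split(tab, 0.3, seed = 4)
  expect_identical(s1$test, s2$test)
  expect_error(stratified_split(tab, 1.2), "test_frac")
  # single-row experiments stay in training with a warning
  tab2 <- rbind(tab, data.frame(experiment_id = "solo", viability = 0.9))
  expect_warning(s3 <- stratified_split(tab2, 0.3, seed = 4), "single-row")
  expect_true(which(tab2$experiment_id == "solo") %in% s3$train)
})

test_that("the z-score scaler uses training statistics with population sd", {
  sc <- fit_scaler(data.frame(x = c(1, 2, 3)))
  scaled <- scale_apply(sc, data.frame(x = c(1, 2, 3)))
  expect_equal(as.numeric(scaled), c(-1, 0, 1) * sqrt(3 / 2),
               tolerance = 1e-12)
  # test value at the training mean maps to zero
  expect_equal(as.numeric(scale_apply(sc, data.frame(x = 2))), 0)
  # transformed training columns have mean 0 and population sd 1
  set.seed(8)
  tr <- data.frame(a = rnorm(50, 5, 3), b = runif(50))
  sc2 <- fit_scaler(tr)
  z <- scale_apply(sc2, tr)
  expect_lt(max(abs(colMeans(z))), 1e-10)
  pop_sd <- apply(z, 2, function(v) sqrt(mean((v - mean(v))^2)))
  expect_lt(max(abs(pop_sd - 1)), 1e-10)
  # round trip
  expect_lt(max(abs(scale_invert(sc2, z) - as.matrix(tr))), 1e-10)
  # constant columns pass through with a warning
  expect_warning(sc3 <- fit_scaler(data.frame(k = rep(7, 5))), "constant")
  expect_equal(as.numeric(scale_apply(sc3, data.frame(k = 7))), 7)
})

test_that("descriptor joining matches particles by phase and nearest
           diameter", {
  rec <- make_records()
  cells <- toy_unit_cells()
  parts <- unique(rec[, c("phase", "core_diameter")])
  names(parts) <- c("phase", "diameter_nm")
  dt <- descriptor_table(cells, parts)
  joined <- join_descriptors(rec, dt)
  expect_equal(nrow(joined), nrow(rec))
  expect_true(all(paste0("D", 1:57) %in% names(joined)))
  # rows of one particle all share the same descriptor values
  one <- joined[joined$phase == parts$phase[1] &
                  joined$core_diameter == parts$diameter_nm[1], "D1"]
  expect_equal(length(unique(one)), 1L)
  # unmatched particle errors with the offending pair
  odd <- rec[1, ]
  odd$core_diameter <- 30
  expect_error(join_descriptors(odd, dt), "Fe.*30")
  # duplicated descriptor rows are ambiguous
  expect_error(join_descriptors(rec, rbind(dt, dt)), "ambiguous")
  expect_error(join_descriptors(rec, dt[0, ]), "empty")
})
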