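#' Toy crystal structures for the three carbide phase labels
#'
#' Three minimal, fully synthetic lattices stand in for the iron carbide
#' phases so the whole workflow runs without external downloads: a simple
#' cubic one-site Fe cell (labelled `Fe2C`), an fcc four-site Fe cell
#' (`Fe3C`) and a P1 orthorhombic two-species Fe/C cell (`Fe5C2`). These
#' are *not* the real crystal structures of the carbide phases - they are
#' synthetic stand-ins with the right plumbing (phase labels, species,
#' densities of the right order) for testing and simulation.
#'
#' @return named list of [unit_cell()] objects.
#' @export
toy_unit_cells <- function() {
  sc <- unit_cell(lattice_from_parameters(2.9, 2.9, 2.9),
                  data.frame(species = "Fe", fx = 0, fy = 0, fz = 0),
                  phase_id = "Fe2C")
  fcc <- unit_cell(lattice_from_parameters(4.4, 4.4, 4.4),
                   data.frame(species = "Fe",
                              fx = c(0, 0.5, 0.5, 0),
                              fy = c(0, 0.5, 0, 0.5),
                              fz = c(0, 0, 0.5, 0.5)),
                   phase_id = "Fe3C")
  ortho <- unit_cell(lattice_from_parameters(4.2, 4.6, 5.0),
                     data.frame(species = c("Fe", "C"),
                                fx = c(0, 0.5), fy = c(0, 0.5),
                                fz = c(0, 0.5)),
                     phase_id = "Fe5C2")
  list(Fe2C = sc, Fe3C = fcc, Fe5C2 = ortho)
}

#' Write the toy CIF fixtures
#'
#' Serialises [toy_unit_cells()] as plain-text CIF files
#' (`<phase>_synthetic.cif`); each round-trips through [parse_cif()].
#'
#' @param dir output directory (created if needed).
#' @return named character vector of file paths.
#' @export
make_toy_cifs <- function(dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cells <- toy_unit_cells()
  paths <- vapply(names(cells), function(ph) {
    p <- file.path(dir, paste0(ph, "_synthetic.cif"))
    write_cif(cells[[ph]], p)
    p
  }, "")
  paths
}

#' Simulation scenario for the synthetic viability dataset
#'
#' Defines the generating process: a log2-spaced concentration ladder, a
#' Hill dose-response
#' `viability = 1 / (1 + (C / IC50_eff)^h) + eps`,
#' `IC50_eff = ic50_base * coating multiplier * (diameter / 20 nm)^gamma`,
#' Gaussian noise clipped at zero. Defaults reproduce the statistical
#' shape the analysis assumes: 186 rows, twelve (phase, diameter)
#' particles, coating-modulated dose response, and a cytotoxic fraction
#' (viability < 70 %) near 18.3 %.
#'
#' @param n_rows total treatments.
#' @param particles data.frame `phase`, `diameter_nm`.
#' @param concentrations dose ladder (ug/mL).
#' @param ic50_base base IC50 (ug/mL).
#' @param hill Hill slope.
#' @param gamma size exponent on `diameter / 20 nm`.
#' @param coating_multipliers named multipliers per coating group.
#' @param noise_sd Gaussian noise sd on the viability fraction.
#' @param cytotoxic_target intended cytotoxic fraction (checked, warned if
#'   infeasible).
#' @param seed integer seed.
#' @return A `sim_scenario` list.
#' @export
sim_scenario <- function(n_rows = 186,
                         particles = expand.grid(
                           phase = c("Fe2C", "Fe3C", "Fe5C2"),
                           diameter_nm = c(4.9, 5.5, 6.2, 7.0),
                           stringsAsFactors = FALSE),
                         concentrations = 3.125 * 2^(0:6),
                         ic50_base = 300,
                         hill = 1.3,
                         gamma = 0.3,
                         coating_multipliers = c(
                           bare = 0.6, `polymer-based` = 1.4,
                           `protein-based` = 1.7, other = 1.0),
                         noise_sd = 0.06,
                         cytotoxic_target = 0.183,
                         seed = 7L) {
  stopif(any(concentrations <= 0) || ic50_base <= 0 || hill <= 0,
         "scenario rates must be positive")
  structure(as.list(environment()), class = "sim_scenario")
}

# coating strings per group, cycled over experiments
sim_coatings <- function() {
  data.frame(
    coating = c("none", "PEG", "pluronic acid", "bovine serum albumin",
                "doxorubicin conjugate", "none", "polyethylene glycol",
                "albumin corona"),
    stringsAsFactors = FALSE
  )
}

sim_cell_lines <- function() {
  data.frame(
    cell_line = c("HeLa", "MCF-7", "L929", "RAW264.7", "A549"),
    organism = c("human", "human", "murine", "murine", "human"),
    health_status = c("cancer", "cancer", "normal", "normal", "cancer"),
    stringsAsFactors = FALSE
  )
}

#' Simulate the dose-response viability table
#'
#' Experiments cycle deterministically over (particle, coating, cell line,
#' shell) combinations; each experiment runs the concentration ladder until
#' `n_rows` treatments exist. The same seed yields a byte-identical table.
#' The attached `manifest` attribute records every generating parameter
#' (including the effective IC50 per experiment) so feature-importance
#' recovery is checkable.
#'
#' @param scenario a [sim_scenario()].
#' @return data.frame of viability records (see [read_viability_csv()] for
#'   the column dictionary) with attribute `manifest`.
#' @export
simulate_viability <- function(scenario = sim_scenario()) {
  s <- scenario
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(derive_seed(s$seed, "sim"))

  coats <- sim_coatings()
  lines <- sim_cell_lines()
  shells <- data.frame(
    shell_material = c("carbon", "iron oxide", "silica", "none"),
    shell_thickness = c(2.5, 2.0, 2.2, 0),
    stringsAsFactors = FALSE
  )
  n_exp <- ceiling(s$n_rows / length(s$concentrations))
  rows <- vector("list", n_exp)
  manifest_rows <- vector("list", n_exp)
  made <- 0L
  for (e in seq_len(n_exp)) {
    pt <- s$particles[(e - 1L) %% nrow(s$particles) + 1L, ]
    co <- coats[(e - 1L) %% nrow(coats) + 1L, , drop = FALSE]
    cl <- lines[(e - 1L) %% nrow(lines) + 1L, ]
    sh <- shells[(e - 1L) %% nrow(shells) + 1L, ]
    grp <- coating_group_of(co$coating)
    ic50_eff <- s$ic50_base * s$coating_multipliers[[grp]] *
      (pt$diameter_nm / 20)^s$gamma
    conc <- s$concentrations[seq_len(min(length(s$concentrations),
                                         s$n_rows - made))]
    v_true <- 1 / (1 + (conc / ic50_eff)^s$hill)
    v <- pmax(0, v_true + stats::rnorm(length(conc), 0, s$noise_sd))
    rows[[e]] <- data.frame(
      experiment_id = sprintf("EXP%02d", e),
      phase = pt$phase,
      core_diameter = pt$diameter_nm,
      size_sd = round(0.05 * pt$diameter_nm + 0.2, 3),
      shell_material = sh$shell_material,
      shell_thickness = sh$shell_thickness,
      coating = co$coating,
      concentration = conc,
      cell_line = cl$cell_line,
      organism = cl$organism,
      health_status = cl$health_status,
      viability = round(v, 4),
      stringsAsFactors = FALSE
    )
    manifest_rows[[e]] <- data.frame(
      experiment_id = sprintf("EXP%02d", e), coating_group = grp,
      ic50_eff = ic50_eff, stringsAsFactors = FALSE)
    made <- made + length(conc)
    if (made >= s$n_rows) { rows <- rows[seq_len(e)]; break }
  }
  out <- do.call(rbind, rows)
  frac <- mean(out$viability < 0.70)
  if (abs(frac - s$cytotoxic_target) > 0.05)
    warning(sprintf(
      "achieved cytotoxic fraction %.3f differs from target %.3f by more than 5 points",
      frac, s$cytotoxic_target), call. = FALSE)
  attr(out, "manifest") <- list(
    scenario = unclass(s)[setdiff(names(unclass(s)), "particles")],
    particles = s$particles,
    experiments = do.call(rbind, manifest_rows),
    achieved_cytotoxic_fraction = frac
  )
  out
}

#' @rdname simulate_viability
#' @param table a simulated table.
#' @param path CSV output path (the `manifest` attribute is not written).
#' @export
write_viability_csv <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}
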