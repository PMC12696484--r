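#' Spherical nanoparticles carved from a crystal lattice
#'
#' A `nanoparticle` is a finite cloud of atoms: Cartesian positions
#' (Angstrom), species labels, core/shell region labels, the nominal
#' diameter and the carving center.
#'
#' @param positions n x 3 numeric matrix (Angstrom).
#' @param species character vector of element symbols, length n.
#' @param nominal_diameter nominal particle diameter (Angstrom).
#' @param center 3-vector, carving center (Angstrom).
#' @param region optional character vector in `{"core", "shell"}`.
#' @param phase_id phase label carried over from the unit cell.
#' @return An object of class `nanoparticle`.
#' @export
nanoparticle <- function(positions, species, nominal_diameter, center,
                         region = NULL, phase_id = "unknown") {
  positions <- as.matrix(positions)
  stopif(nrow(positions) < 1L, "nanoparticle needs at least one atom")
  stopif(ncol(positions) != 3L, "positions must be n x 3")
  stopif(length(species) != nrow(positions), "species/positions length mismatch")
  r <- sqrt(rowSums(sweep(positions, 2, center)^2))
  stopif(any(r > nominal_diameter / 2 + 1e-6),
         "atom(s) outside the nominal radius")
  if (!is.null(region))
    stopif(!all(region %in% c("core", "shell")) ||
             length(region) != nrow(positions),
           "region must partition atoms into core/shell")
  structure(
    list(positions = positions, species = as.character(species),
         region = region, nominal_diameter = nominal_diameter,
         center = as.numeric(center), phase_id = phase_id),
    class = "nanoparticle"
  )
}

#' @export
print.nanoparticle <- function(x, ...) {
  cat("<nanoparticle> phase:", x$phase_id,
      " d =", format(x$nominal_diameter, digits = 5), "A,",
      nrow(x$positions), "atoms\n")
  if (!is.null(x$region)) {
    tb <- table(factor(x$region, c("core", "shell")))
    cat("  core:", tb[["core"]], " shell:", tb[["shell"]], "\n")
  }
  invisible(x)
}

#' Number of atoms in a nanoparticle
#' @param np a [nanoparticle()].
#' @export
n_atoms <- function(np) nrow(np$positions)

#' Replicate a unit cell into a supercell
#'
#' `reps` translated copies of the cell contents along each lattice vector;
#' the atom count is exactly `reps^3` times the merged site count.
#'
#' @param cell a [unit_cell()].
#' @param reps positive integer, replications per axis (scalar or length 3).
#' @return list with `positions` (Cartesian, Angstrom) and `species`.
#' @export
build_supercell <- function(cell, reps) {
  reps <- as.integer(rep(reps, length.out = 3))
  stopif(any(reps <= 0L), "reps must be positive integers")
  frac <- as.matrix(cell$sites[, c("fx", "fy", "fz")])
  shifts <- as.matrix(expand.grid(0:(reps[1] - 1L), 0:(reps[2] - 1L),
                                  0:(reps[3] - 1L)))
  n_site <- nrow(frac)
  all_frac <- shifts[rep(seq_len(nrow(shifts)), each = n_site), , drop = FALSE] +
    frac[rep(seq_len(n_site), times = nrow(shifts)), , drop = FALSE]
  list(
    positions = all_frac %*% cell$lattice,
    species = rep(cell$sites$species, times = nrow(shifts))
  )
}

# Perpendicular heights of the cell along each axis: distance between
# opposite faces, used to size the supercell so a sphere fits.
cell_heights <- function(cell) {
  lat <- cell$lattice
  v <- abs(det(lat))
  cr <- function(u, w) c(u[2] * w[3] - u[3] * w[2],
                         u[3] * w[1] - u[1] * w[3],
                         u[1] * w[2] - u[2] * w[1])
  c(v / sqrt(sum(cr(lat[2, ], lat[3, ])^2)),
    v / sqrt(sum(cr(lat[1, ], lat[3, ])^2)),
    v / sqrt(sum(cr(lat[1, ], lat[2, ])^2)))
}

#' Carve a spherical nanoparticle out of a supercell
#'
#' Replicates the cell so the supercell extends at least `diameter + 2 * margin`
#' along every axis, then keeps atoms within `diameter / 2` (inclusive, with
#' a 1e-8 Angstrom tolerance) of the center.
#'
#' @param cell a [unit_cell()].
#' @param diameter target particle diameter (Angstrom).
#' @param center_policy `"supercell"` (geometric center of the supercell,
#'   the default), `"atom"` (the atom nearest that center), or a numeric
#'   3-vector of Cartesian coordinates.
#' @param margin extra supercell margin (Angstrom).
#' @return A [nanoparticle()] without region labels; see
#'   [partition_core_shell()].
#' @export
carve_sphere <- function(cell, diameter, center_policy = "supercell",
                         margin = 1) {
  stopif(diameter <= 0, "diameter must be positive")
  heights <- cell_heights(cell)
  reps <- pmax(1L, as.integer(ceiling((diameter + 2 * margin) / heights)))
  sc <- build_supercell(cell, reps)
  if (is.numeric(center_policy)) {
    center <- as.numeric(center_policy)
    stopif(length(center) != 3L, "numeric center must be a 3-vector")
  } else {
    box_center <- as.numeric((reps %*% cell$lattice) / 2)
    center <- switch(match.arg(center_policy, c("supercell", "atom")),
      supercell = box_center,
      atom = {
        d <- rowSums(sweep(sc$positions, 2, box_center)^2)
        as.numeric(sc$positions[which.min(d), ])
      })
  }
  r <- sqrt(rowSums(sweep(sc$positions, 2, center)^2))
  keep <- r <= diameter / 2 + 1e-8
  stopif(!any(keep),
         "empty particle: no atom within the requested diameter (",
         format(diameter), " A) of the center")
  nanoparticle(sc$positions[keep, , drop = FALSE], sc$species[keep],
               nominal_diameter = diameter, center = center,
               phase_id = cell$phase_id)
}

#' Label core and shell atoms
#'
#' The shell is the surface layer: atom i is shell iff
#' `||r_i - center|| >= R - shell_depth` with `R = nominal_diameter / 2`
#' (inclusive toward the shell); all other atoms are core.
#'
#' @param np a [nanoparticle()].
#' @param shell_depth shell thickness measured inward from the nominal
#'   radius (Angstrom); default 4.
#' @return The particle with its `region` field filled in.
#' @export
partition_core_shell <- function(np, shell_depth = 4) {
  stopif(shell_depth < 0, "shell_depth must be non-negative")
  r <- sqrt(rowSums(sweep(np$positions, 2, np$center)^2))
  boundary <- np$nominal_diameter / 2 - shell_depth
  np$region <- ifelse(r >= boundary - 1e-9, "shell", "core")
  np
}

#' Write a nanoparticle as extended XYZ
#'
#' Standard XYZ with a comment line carrying phase and diameter and a
#' trailing per-atom region column when regions are assigned.
#'
#' @param np a [nanoparticle()].
#' @param path output file; when `NULL` the text is returned.
#' @export
write_xyz <- function(np, path = NULL) {
  n <- n_atoms(np)
  header <- sprintf("phase=%s diameter_A=%.6f", np$phase_id,
                    np$nominal_diameter)
  body <- if (is.null(np$region)) {
    sprintf("%s %.8f %.8f %.8f", np$species,
            np$positions[, 1], np$positions[, 2], np$positions[, 3])
  } else {
    sprintf("%s %.8f %.8f %.8f %s", np$species,
            np$positions[, 1], np$positions[, 2], np$positions[, 3],
            np$region)
  }
  lines <- c(as.character(n), header, body)
  if (is.null(path)) return(paste(lines, collapse = "\n"))
  writeLines(lines, path)
  invisible(path)
}
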