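#' Reference pair-potential energy model
#'
#' The descriptor machinery is generic over an *energy model*: a list with
#' `per_atom_energy(positions, species)` returning n per-atom energies (eV)
#' and `bulk_energy_per_atom(cell)` returning the periodic bulk cohesive
#' energy per atom (eV, minimal image). Any interatomic-potential engine can
#' be adapted to this contract; the built-in reference implementation is a
#' cut-off pairwise Lennard-Jones (default) or Morse potential with
#' per-species-pair parameters, with each pair energy half-assigned to both
#' partners: `E_i = 1/2 * sum_{j != i} phi(r_ij)`.
#'
#' @param params named list of species-pair parameter lists. Names are
#'   `"A-B"` with A, B element symbols in either order; each entry needs
#'   `epsilon` (eV) and `sigma` (Angstrom) for Lennard-Jones, or `D`
#'   (eV), `a` (1/Angstrom) and `r0` (Angstrom) for Morse.
#' @param cutoff interaction cutoff (Angstrom).
#' @param type `"lj"` or `"morse"`.
#' @return An object of class `energy_model`.
#' @examples
#' m <- pair_potential_model()
#' # LJ dimer at its minimum r = 2^(1/6) sigma: per-atom energy -epsilon/2
#' r <- 2^(1/6) * 2.3
#' m$per_atom_energy(rbind(c(0, 0, 0), c(r, 0, 0)), c("Fe", "Fe"))
#' @export
pair_potential_model <- function(params = default_pair_params(),
                                 cutoff = 6, type = c("lj", "morse")) {
  type <- match.arg(type)
  stopif(cutoff <= 0, "cutoff must be positive")

  pair_key <- function(a, b) {
    ab <- sort(c(a, b))
    paste(ab[1], ab[2], sep = "-")
  }
  get_par <- function(a, b) {
    key <- pair_key(a, b)
    p <- params[[key]]
    stopif(is.null(p), "missing pair-potential parameters for species pair ",
           key)
    p
  }
  phi <- function(r, p) {
    if (type == "lj") {
      sr6 <- (p$sigma / r)^6
      4 * p$epsilon * (sr6^2 - sr6)
    } else {
      e <- exp(-p$a * (r - p$r0))
      p$D * (e^2 - 2 * e)
    }
  }

  per_atom_energy <- function(positions, species) {
    positions <- as.matrix(positions)
    n <- nrow(positions)
    if (n < 2L) return(numeric(n))
    pr <- pairs_within_cutoff(positions, cutoff)
    if (nrow(pr) == 0L) return(numeric(n))
    si <- species[pr$i]; sj <- species[pr$j]
    keys <- paste(pmin(si, sj), pmax(si, sj), sep = "-")
    e <- numeric(nrow(pr))
    for (key in unique(keys)) {
      sel <- keys == key
      p <- params[[key]]
      stopif(is.null(p), "missing pair-potential parameters for species pair ",
             key)
      e[sel] <- phi(pr$d[sel], p)
    }
    half <- e / 2
    as.numeric(rowsum(c(half, half), c(pr$i, pr$j),
                      reorder = FALSE)[as.character(seq_len(n)), ]) |>
      (\(x) ifelse(is.na(x), 0, x))()
  }

  bulk_energy_per_atom <- function(cell) {
    # replicate far enough that every image within the cutoff of any central
    # cell atom is present, then sum interactions of central atoms with all
    # other atoms (half-assigned)
    heights <- cell_heights(cell)
    reps <- as.integer(2 * ceiling(cutoff / heights) + 1L)
    sc <- build_supercell(cell, reps)
    mid <- floor(reps / 2)
    # index range of the central copy: sites are ordered cell-by-cell
    shifts <- as.matrix(expand.grid(0:(reps[1] - 1L), 0:(reps[2] - 1L),
                                    0:(reps[3] - 1L)))
    central_block <- which(shifts[, 1] == mid[1] & shifts[, 2] == mid[2] &
                             shifts[, 3] == mid[3])
    ns <- nrow(cell$sites)
    central <- ((central_block - 1L) * ns + 1L):(central_block * ns)
    e <- numeric(length(central))
    for (ci in seq_along(central)) {
      i <- central[ci]
      dv <- sweep(sc$positions, 2, sc$positions[i, ])
      r <- sqrt(rowSums(dv^2))
      sel <- which(r <= cutoff & r > 1e-9)
      if (!length(sel)) next
      ei <- 0
      for (j in sel) ei <- ei + phi(r[j], get_par(sc$species[i],
                                                  sc$species[j]))
      e[ci] <- ei / 2
    }
    mean(e)
  }

  structure(list(per_atom_energy = per_atom_energy,
                 bulk_energy_per_atom = bulk_energy_per_atom,
                 params = params, cutoff = cutoff, type = type),
            class = "energy_model")
}

#' Default Lennard-Jones parameters for Fe/C pairs
#'
#' Reference values sized so the potential minimum sits near typical
#' interatomic spacings of the toy lattices; cross terms follow
#' Lorentz-Berthelot combination.
#' @export
default_pair_params <- function() {
  list(
    `Fe-Fe` = list(epsilon = 0.40, sigma = 2.30),
    `C-C`   = list(epsilon = 0.25, sigma = 1.90),
    `C-Fe`  = list(epsilon = sqrt(0.40 * 0.25), sigma = (2.30 + 1.90) / 2)
  )
}

#' Per-atom pair energies for arbitrary coordinates
#'
#' Thin functional wrapper over [pair_potential_model()] for one-off
#' evaluations.
#'
#' @param positions n x 3 Cartesian matrix (Angstrom).
#' @param species element symbols, length n.
#' @param params,cutoff,type forwarded to [pair_potential_model()].
#' @return numeric vector of per-atom energies (eV); their sum is the total
#'   potential energy.
#' @export
reference_pair_energy <- function(positions, species,
                                  params = default_pair_params(),
                                  cutoff = 6, type = "lj") {
  pair_potential_model(params, cutoff, type)$per_atom_energy(positions,
                                                             species)
}

#' Optional steepest-descent relaxation
#'
#' Off by default everywhere; provided as a hook for energy-minimised
#' particle geometries. Forces are computed by central finite differences
#' of the model's total energy.
#'
#' @param np a [nanoparticle()].
#' @param model an energy model.
#' @param max_steps iteration cap.
#' @param force_tol convergence threshold on the max force component
#'   (eV/Angstrom).
#' @param step_size displacement per unit force (Angstrom^2/eV).
#' @return The relaxed particle (positions updated in place).
#' @export
relax_particle <- function(np, model, max_steps = 200, force_tol = 1e-3,
                           step_size = 0.05) {
  pos <- np$positions
  h <- 1e-5
  total_e <- function(p) sum(model$per_atom_energy(p, np$species))
  for (step in seq_len(max_steps)) {
    grad <- matrix(0, nrow(pos), 3)
    for (i in seq_len(nrow(pos))) for (k in 1:3) {
      pp <- pos; pp[i, k] <- pp[i, k] + h
      pm <- pos; pm[i, k] <- pm[i, k] - h
      grad[i, k] <- (total_e(pp) - total_e(pm)) / (2 * h)
    }
    if (max(abs(grad)) < force_tol) break
    pos <- pos - step_size * grad
  }
  np$positions <- pos
  np
}
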