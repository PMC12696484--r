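#' The 57-entry atomistic descriptor registry
#'
#' Enumerates the descriptor vector: id (D1-D57), quantity family, region
#' (`all` / `core` / `shell`, or a core-shell `diff` / `ratio`), neighbor
#' cutoff, harmonic order and units. Only eight ids have externally fixed
#' meanings, and the registry places them at their externally fixed positions:
#'
#' * D5  - average potential energy of the core atoms (eV)
#' * D7  - average core-minus-shell potential-energy difference (eV)
#' * D15 - average coordination parameter (3 A) of the core atoms
#' * D21 - average coordination parameter (4 A) of the shell atoms
#' * D32 - lattice energy of the nanoparticle (eV, per atom)
#' * D33 - bulk lattice energy minus nanoparticle lattice energy (eV)
#' * D46 - average second hexatic (l = 6) order parameter, all atoms
#' * D48 - average second hexatic (l = 6) order parameter, shell atoms
#'
#' The remaining ids are filled by (all, core, shell, difference, ratio)
#' families over atom counts, potential energy, coordination at 3/4/5 A,
#' a species-radius-scaled minimum-cutoff coordination variant, lattice
#' energies, sphere geometry and the l = 4 / l = 6 order parameters (both
#' Steinhardt q and planar psi variants). The registry is configuration: it
#' is an ordinary data.frame that can be amended as long as 57 rows remain.
#'
#' @return data.frame with one row per descriptor, columns `id`, `quantity`,
#'   `region`, `cutoff`, `l`, `variant`, `units`, `label`.
#' @export
descriptor_registry <- function() {
  row <- function(id, quantity, region = NA, cutoff = NA, l = NA,
                  variant = NA, units = "", label = "") {
    data.frame(id = id, quantity = quantity, region = region,
               cutoff = cutoff, l = l, variant = variant, units = units,
               label = label, stringsAsFactors = FALSE)
  }
  regions5 <- function(base_id, quantity, cutoff = NA, l = NA, variant = NA,
                       units = "", what = "") {
    regs <- c("all", "core", "shell", "diff", "ratio")
    do.call(rbind, lapply(seq_along(regs), function(k)
      row(paste0("D", base_id + k - 1L), quantity, regs[k], cutoff, l,
          variant, units,
          paste0(what, " (", regs[k], ")"))))
  }
  reg <- rbind(
    row("D1", "n_atoms", "all", units = "count", label = "atom count (all)"),
    row("D2", "n_atoms", "core", units = "count", label = "atom count (core)"),
    row("D3", "n_atoms", "shell", units = "count", label = "atom count (shell)"),
    row("D4", "avg_pe", "all", units = "eV",
        label = "average potential energy (all)"),
    row("D5", "avg_pe", "core", units = "eV",
        label = "average potential energy of the core atoms"),
    row("D6", "avg_pe", "shell", units = "eV",
        label = "average potential energy (shell)"),
    row("D7", "avg_pe", "diff", units = "eV",
        label = "core-shell average potential energy difference"),
    row("D8", "avg_pe", "ratio", units = "",
        label = "core/shell average potential energy ratio"),
    row("D9", "n_atoms", "ratio", units = "",
        label = "core/shell atom count ratio"),
    row("D10", "n_frac", "core", units = "",
        label = "core atom fraction"),
    row("D11", "n_frac", "shell", units = "",
        label = "shell atom fraction"),
    row("D12", "n_atoms", "diff", units = "count",
        label = "core-shell atom count difference"),
    row("D13", "total_pe", "all", units = "eV",
        label = "total potential energy"),
    regions5(14, "coordination", cutoff = 3, units = "count",
             what = "coordination parameter (3 A)"),
    regions5(19, "coordination", cutoff = 4, units = "count",
             what = "coordination parameter (4 A)"),
    regions5(24, "coordination", cutoff = 5, units = "count",
             what = "coordination parameter (5 A)"),
    row("D29", "bulk_lattice_energy", NA, units = "eV",
        label = "lattice energy of the bulk material (per atom)"),
    row("D30", "pe_sd", "all", units = "eV",
        label = "per-atom potential energy spread (all)"),
    row("D31", "pe_sd", "shell", units = "eV",
        label = "per-atom potential energy spread (shell)"),
    row("D32", "np_lattice_energy", NA, units = "eV",
        label = "lattice energy of the nanoparticle (per atom)"),
    row("D33", "bulk_minus_np_lattice", NA, units = "eV",
        label = "bulk minus nanoparticle lattice energy"),
    regions5(34, "coordination_species", cutoff = NA, units = "count",
             what = "coordination at 1.2 x covalent-radius-sum cutoff"),
    row("D39", "volume", NA, units = "A^3", label = "nanoparticle volume"),
    row("D40", "surface_area", NA, units = "A^2",
        label = "nanoparticle surface area"),
    regions5(41, "bond_order", cutoff = 4, l = 4, variant = "steinhardt",
             what = "first hexatic order parameter (l = 4)"),
    row("D46", "bond_order", "all", cutoff = 4, l = 6,
        variant = "steinhardt",
        label = "average second hexatic order parameter of all atoms"),
    row("D47", "bond_order", "core", cutoff = 4, l = 6,
        variant = "steinhardt",
        label = "average second hexatic order parameter of the core atoms"),
    row("D48", "bond_order", "shell", cutoff = 4, l = 6,
        variant = "steinhardt",
        label = "average second hexatic order parameter of the shell atoms"),
    row("D49", "bond_order", "diff", cutoff = 4, l = 6,
        variant = "steinhardt",
        label = "core-shell second hexatic order difference"),
    row("D50", "bond_order", "ratio", cutoff = 4, l = 6,
        variant = "steinhardt",
        label = "core/shell second hexatic order ratio"),
    row("D51", "surface_to_volume", NA, units = "1/A",
        label = "surface-to-volume ratio"),
    row("D52", "radius", NA, units = "A", label = "nominal radius"),
    row("D53", "atom_density", NA, units = "1/A^3",
        label = "atom number density"),
    row("D54", "surface_atom_density", NA, units = "1/A^2",
        label = "shell atoms per surface area"),
    row("D55", "bond_order", "all", cutoff = 4, l = 6, variant = "planar",
        label = "planar psi6 order parameter (all)"),
    row("D56", "bond_order", "shell", cutoff = 4, l = 6, variant = "planar",
        label = "planar psi6 order parameter (shell)"),
    row("D57", "bond_order", "core", cutoff = 4, l = 6, variant = "planar",
        label = "planar psi6 order parameter (core)")
  )
  rownames(reg) <- NULL
  reg
}
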