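region_index <- function(np, region) {
  stopif(is.null(np$region) && region %in% c("core", "shell"),
         "particle has no core/shell labels; call partition_core_shell()")
  switch(region,
         all = seq_len(n_atoms(np)),
         core = which(np$region == "core"),
         shell = which(np$region == "shell"),
         stop("unknown region: ", region))
}

#' Mean coordination number over a region
#'
#' Neighbors are counted against *all* atoms of the particle regardless of
#' region; only the averaging is restricted. An empty region yields `NA`
#' with a `missing` attribute rather than an error, so descriptor vectors
#' can flag rather than fail.
#'
#' @param np a [nanoparticle()] with region labels for core/shell queries.
#' @param cutoff neighbor cutoff (Angstrom).
#' @param region `"all"`, `"core"` or `"shell"`.
#' @export
coordination_descriptor <- function(np, cutoff, region = "all") {
  idx <- region_index(np, region)
  if (length(idx) == 0L) return(structure(NA_real_, missing = "empty region"))
  counts <- neighbor_counts(np, cutoff)
  mean(counts[idx])
}

# Species-aware variant: atom j is a neighbor of i iff
# r_ij <= scale * (r_cov(i) + r_cov(j)). Mirrors minimum-cutoff coordination
# rules tied to covalent radii.
covalent_radii <- c(Fe = 1.32, C = 0.76, O = 0.66, Si = 1.11, Mn = 1.39)

#' @rdname coordination_descriptor
#' @param scale multiplier on the covalent-radius sum for the
#'   species-resolved variant.
#' @export
coordination_species_descriptor <- function(np, region = "all", scale = 1.2) {
  idx <- region_index(np, region)
  if (length(idx) == 0L) return(structure(NA_real_, missing = "empty region"))
  rc <- covalent_radii[np$species]
  stopif(any(is.na(rc)), "no covalent radius for species: ",
         paste(unique(np$species[is.na(rc)]), collapse = ", "))
  maxcut <- scale * 2 * max(rc)
  pr <- pairs_within_cutoff(np$positions, maxcut)
  ok <- pr$d <= scale * (rc[pr$i] + rc[pr$j])
  counts <- tabulate(c(pr$i[ok], pr$j[ok]), nbins = n_atoms(np))
  mean(counts[idx])
}

#' Mean bond-orientational order over a region
#'
#' @param np a [nanoparticle()].
#' @param l harmonic order (6 for the "second hexatic" parameter, 4 for the
#'   first).
#' @param cutoff neighbor cutoff (Angstrom), default 4.
#' @param region `"all"`, `"core"` or `"shell"`.
#' @param variant `"steinhardt"` (3-D spherical-harmonic invariant,
#'   default) or `"planar"` (xy-plane psi_l).
#' @param pairs optional precomputed pair list.
#' @export
bond_order_descriptor <- function(np, l = 6, cutoff = 4, region = "all",
                                  variant = c("steinhardt", "planar"),
                                  pairs = NULL) {
  variant <- match.arg(variant)
  idx <- region_index(np, region)
  if (length(idx) == 0L) return(structure(NA_real_, missing = "empty region"))
  q <- if (variant == "steinhardt") {
    per_atom_ql(np$positions, l, cutoff, pairs)
  } else {
    per_atom_psil(np$positions, l, cutoff, pairs)
  }
  mean(q[idx])
}

#' Potential-energy statistics over particle regions
#'
#' @param np a [nanoparticle()] with region labels.
#' @param model an energy model (see [pair_potential_model()]).
#' @return list with `avg_all`, `avg_core`, `avg_shell`,
#'   `diff` (= core - shell, eV; signs preserved) and the per-atom energies.
#'   Empty regions flag the affected entries as `NA`.
#' @export
energy_statistics <- function(np, model) {
  e <- model$per_atom_energy(np$positions, np$species)
  core <- region_index(np, "core"); shell <- region_index(np, "shell")
  avg <- function(ix) if (length(ix)) mean(e[ix]) else NA_real_
  ac <- avg(core); as_ <- avg(shell)
  list(avg_all = mean(e), avg_core = ac, avg_shell = as_,
       diff = ac - as_, per_atom = e)
}

#' Nanoparticle and bulk lattice energies
#'
#' The nanoparticle lattice energy is the total particle energy divided by
#' the atom count (eV per atom, sign preserved); the companion descriptor is
#' `bulk - NP`, negative when under-coordinated surface atoms raise the
#' particle's per-atom energy above the periodic bulk value.
#'
#' @param np a [nanoparticle()].
#' @param cell the source [unit_cell()].
#' @param model an energy model supporting periodic bulk evaluation.
#' @return list with `np_lattice_energy`, `bulk_lattice_energy`,
#'   `bulk_minus_np`.
#' @export
lattice_energy_descriptors <- function(np, cell, model) {
  e <- model$per_atom_energy(np$positions, np$species)
  np_le <- sum(e) / n_atoms(np)
  bulk <- model$bulk_energy_per_atom(cell)
  list(np_lattice_energy = np_le, bulk_lattice_energy = bulk,
       bulk_minus_np = bulk - np_le)
}

#' Sphere geometry and count descriptors
#'
#' Volume and surface area come from the nominal diameter
#' (`V = 4/3 pi (d/2)^3`, `A = 4 pi (d/2)^2`); ratios with an empty
#' denominator region are flagged `NA` instead of dividing by zero.
#'
#' @param np a [nanoparticle()] with region labels.
#' @export
geometry_descriptors <- function(np) {
  R <- np$nominal_diameter / 2
  n <- n_atoms(np)
  nc <- length(region_index(np, "core"))
  ns <- length(region_index(np, "shell"))
  vol <- 4 / 3 * pi * R^3
  area <- 4 * pi * R^2
  list(n_all = n, n_core = nc, n_shell = ns,
       volume = vol, surface_area = area,
       surface_to_volume = area / vol,
       core_shell_ratio = if (ns > 0 && nc > 0) nc / ns else NA_real_,
       radius = R, atom_density = n / vol,
       surface_atom_density = ns / area)
}

#' Compute the full 57-entry descriptor vector
#'
#' Evaluates every registry row on one particle. Values whose defining
#' region is empty (or whose denominator vanishes) are `NA` and listed in
#' the `missing` attribute; they are never silently zeroed.
#'
#' @param np a [nanoparticle()] with region labels.
#' @param cell the source [unit_cell()] (for the bulk lattice energy).
#' @param model an energy model; default [pair_potential_model()].
#' @param registry descriptor registry; must have exactly 57 rows.
#' @return named numeric vector `D1...D57` with attributes `missing`
#'   (character vector of flagged ids) and `registry`.
#' @export
compute_descriptor_vector <- function(np, cell,
                                      model = pair_potential_model(),
                                      registry = descriptor_registry()) {
  stopif(nrow(registry) != 57L,
         "descriptor registry must define exactly 57 descriptors, got ",
         nrow(registry))
  stopif(anyDuplicated(registry$id) > 0L, "registry ids must be unique")
  stopif(is.null(np$region), "particle must have core/shell labels")

  es <- energy_statistics(np, model)
  # reuse the per-atom energies rather than re-evaluating the model
  np_le <- sum(es$per_atom) / n_atoms(np)
  bulk <- model$bulk_energy_per_atom(cell)
  le <- list(np_lattice_energy = np_le, bulk_lattice_energy = bulk,
             bulk_minus_np = bulk - np_le)
  geo <- geometry_descriptors(np)
  core <- region_index(np, "core"); shell <- region_index(np, "shell")

  # one master pair list at the widest cutoff serves every neighbor-based
  # descriptor; filtering it by distance is exact
  cuts <- registry$cutoff[!is.na(registry$cutoff)]
  rc_all <- covalent_radii[np$species]
  max_cut <- max(c(cuts, if (all(!is.na(rc_all))) 1.2 * 2 * max(rc_all)))
  master_pairs <- pairs_within_cutoff(np$positions, max_cut)

  coord_cache <- list(); spec_cache <- list(); bo_cache <- list()
  mean_reg <- function(values, region) {
    pick <- function(ix) if (length(ix)) mean(values[ix]) else NA_real_
    switch(region,
      all = mean(values),
      core = pick(core),
      shell = pick(shell),
      diff = pick(core) - pick(shell),
      ratio = {
        s <- pick(shell)
        if (is.na(s) || s == 0) NA_real_ else pick(core) / s
      })
  }
  coord_values <- function(cutoff) {
    key <- as.character(cutoff)
    if (is.null(coord_cache[[key]])) {
      ok <- master_pairs$d <= cutoff
      coord_cache[[key]] <<- tabulate(c(master_pairs$i[ok],
                                        master_pairs$j[ok]),
                                      nbins = n_atoms(np))
    }
    coord_cache[[key]]
  }
  species_coord_values <- function() {
    if (length(spec_cache) == 0L) {
      ok <- master_pairs$d <=
        1.2 * (rc_all[master_pairs$i] + rc_all[master_pairs$j])
      spec_cache[["v"]] <<- tabulate(c(master_pairs$i[ok],
                                       master_pairs$j[ok]),
                                     nbins = n_atoms(np))
    }
    spec_cache[["v"]]
  }
  bond_order_values <- function(l, cutoff, variant) {
    key <- paste(l, cutoff, variant)
    if (is.null(bo_cache[[key]])) {
      sub <- master_pairs[master_pairs$d <= cutoff, , drop = FALSE]
      bo_cache[[key]] <<- if (variant == "planar") {
        per_atom_psil(np$positions, l, cutoff, pairs = sub)
      } else {
        per_atom_ql(np$positions, l, cutoff, pairs = sub)
      }
    }
    bo_cache[[key]]
  }

  vals <- vapply(seq_len(nrow(registry)), function(k) {
    rw <- registry[k, ]
    switch(rw$quantity,
      n_atoms = switch(rw$region, all = geo$n_all, core = geo$n_core,
                       shell = geo$n_shell, diff = geo$n_core - geo$n_shell,
                       ratio = geo$core_shell_ratio),
      n_frac = switch(rw$region, core = geo$n_core / geo$n_all,
                      shell = geo$n_shell / geo$n_all),
      avg_pe = switch(rw$region, all = es$avg_all, core = es$avg_core,
                      shell = es$avg_shell, diff = es$diff,
                      ratio = if (is.na(es$avg_shell) || es$avg_shell == 0)
                        NA_real_ else es$avg_core / es$avg_shell),
      total_pe = sum(es$per_atom),
      pe_sd = {
        ix <- if (rw$region == "all") seq_along(es$per_atom) else
          region_index(np, rw$region)
        if (length(ix) > 1) stats::sd(es$per_atom[ix]) else NA_real_
      },
      coordination = mean_reg(coord_values(rw$cutoff), rw$region),
      coordination_species = mean_reg(species_coord_values(), rw$region),
      bond_order = mean_reg(bond_order_values(rw$l, rw$cutoff, rw$variant),
                            rw$region),
      bulk_lattice_energy = le$bulk_lattice_energy,
      np_lattice_energy = le$np_lattice_energy,
      bulk_minus_np_lattice = le$bulk_minus_np,
      volume = geo$volume,
      surface_area = geo$surface_area,
      surface_to_volume = geo$surface_to_volume,
      radius = geo$radius,
      atom_density = geo$atom_density,
      surface_atom_density = geo$surface_atom_density,
      stop("registry quantity not implemented: ", rw$quantity)
    )
  }, numeric(1))

  names(vals) <- registry$id
  structure(vals, missing = registry$id[is.na(vals)], registry = registry)
}

#' Descriptor table for a set of particles
#'
#' Builds, carves and partitions one particle per (phase, diameter) request
#' and stacks the descriptor vectors into a data.frame ready to join onto a
#' viability table; write with [write_descriptor_csv()].
#'
#' @param cells named list of [unit_cell()] objects, names = phase ids.
#' @param particles data.frame with columns `phase` and `diameter_nm`.
#' @param model energy model; default [pair_potential_model()].
#' @param registry descriptor registry.
#' @param shell_depth core/shell partition depth (Angstrom).
#' @param center_policy forwarded to [carve_sphere()].
#' @return data.frame: `phase`, `diameter_nm`, `D1`...`D57`, plus a
#'   `missing_flags` column (semicolon-separated flagged ids, empty when
#'   none).
#' @export
descriptor_table <- function(cells, particles,
                             model = pair_potential_model(),
                             registry = descriptor_registry(),
                             shell_depth = 4, center_policy = "supercell") {
  stopif(!all(particles$phase %in% names(cells)),
         "no unit cell for phase(s): ",
         paste(setdiff(particles$phase, names(cells)), collapse = ", "))
  rows <- lapply(seq_len(nrow(particles)), function(k) {
    ph <- particles$phase[k]
    d_nm <- particles$diameter_nm[k]
    np <- carve_sphere(cells[[ph]], diameter = d_nm * 10,
                       center_policy = center_policy)
    np <- partition_core_shell(np, shell_depth)
    v <- compute_descriptor_vector(np, cells[[ph]], model, registry)
    out <- as.data.frame(as.list(v))
    out$phase <- ph
    out$diameter_nm <- d_nm
    out$missing_flags <- paste(attr(v, "missing"), collapse = ";")
    out
  })
  res <- do.call(rbind, rows)
  res[, c("phase", "diameter_nm", registry$id, "missing_flags")]
}

#' @rdname descriptor_table
#' @param tab a [descriptor_table()] result.
#' @param path output CSV path.
#' @export
write_descriptor_csv <- function(tab, path) {
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
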