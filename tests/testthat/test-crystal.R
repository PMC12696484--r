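test_that("a minimal P1 CIF parses to the identity cell", {
  cell <- parse_cif(minimal_cif)
  expect_equal(nrow(cell$sites), 1L)
  expect_equal(cell_volume(cell), 8)
  expect_equal(cell$sites$species, "Fe")
})

test_that("symmetry operators are applied and images wrapped", {
  cif <- paste(
    "data_sym",
    "_cell_length_a 2", "_cell_length_b 2", "_cell_length_c 2",
    "loop_",
    "_symmetry_equiv_pos_as_xyz",
    "'x, y, z'",
    "'-x, -y, -z'",
    "loop_",
    "_atom_site_label",
    "_atom_site_fract_x", "_atom_site_fract_y", "_atom_site_fract_z",
    "Fe1 0.25 0 0",
    sep = "\n")
  cell <- parse_cif(cif)
  expect_equal(nrow(cell$sites), 2L)
  expect_equal(sort(cell$sites$fx), c(0.25, 0.75))
  expect_equal(cell$sites$fy, c(0, 0))
})

test_that("missing cell parameters raise a parse error naming the tag", {
  bad <- sub("_cell_length_a 2\n", "", minimal_cif, fixed = TRUE)
  expect_error(parse_cif(bad), "_cell_length_a")
  expect_error(parse_cif("data_x\n_cell_length_a 2\n_cell_length_b 2\n_cell_length_c 2\n"),
               "_atom_site")
})

test_that("species labels lose oxidation suffixes and duplicates merge", {
  cif <- paste(
    "data_dup",
    "_cell_length_a 3", "_cell_length_b 3", "_cell_length_c 3",
    "loop_",
    "_symmetry_equiv_pos_as_xyz",
    "'x, y, z'",
    "'x, y, z'",
    "loop_",
    "_atom_site_label", "_atom_site_type_symbol",
    "_atom_site_fract_x", "_atom_site_fract_y", "_atom_site_fract_z",
    "Fe1 Fe3+ 0.5 0.5 0.5",
    sep = "\n")
  cell <- parse_cif(cif)
  expect_equal(nrow(cell$sites), 1L)  # duplicate image merged
  expect_equal(cell$sites$species, "Fe")
})

test_that("CIF writing then re-parsing reproduces positions", {
  cells <- toy_unit_cells()
  for (cell in cells) {
    back <- parse_cif(write_cif(cell))
    expect_equal(nrow(back$sites), nrow(cell$sites))
    o1 <- order(cell$sites$fx, cell$sites$fy, cell$sites$fz)
    o2 <- order(back$sites$fx, back$sites$fy, back$sites$fz)
    cart1 <- as.matrix(cell$sites[o1, c("fx", "fy", "fz")]) %*% cell$lattice
    cart2 <- as.matrix(back$sites[o2, c("fx", "fy", "fz")]) %*% back$lattice
    expect_lt(max(abs(cart1 - cart2)), 1e-6)
  }
})

test_that("supercell atom count is exactly reps^3 x site count", {
  expect_length(build_supercell(cubic_cell(), 3)$species, 27L)
  two_site <- unit_cell(lattice_from_parameters(3, 3, 3),
                        data.frame(species = c("Fe", "C"),
                                   fx = c(0, 0.5), fy = c(0, 0.5),
                                   fz = c(0, 0.5)))
  expect_length(build_supercell(two_site, 2)$species, 16L)
  expect_error(build_supercell(cubic_cell(), 0), "positive")
  for (reps in 1:4)
    expect_length(build_supercell(two_site, reps)$species, 2L * reps^3)
})

test_that("sphere carving keeps exactly the atoms inside the radius", {
  np <- carve_sphere(cubic_cell(2), 4, center_policy = "atom")
  expect_equal(n_atoms(np), 7L)
  r <- sqrt(rowSums(sweep(np$positions, 2, np$center)^2))
  expect_true(all(r <= 2 + 1e-8))
  # only the central atom survives a tiny sphere
  np1 <- carve_sphere(cubic_cell(2), 0.5, center_policy = "atom")
  expect_equal(n_atoms(np1), 1L)
  # centered between atoms nothing survives
  expect_error(carve_sphere(cubic_cell(2), 0.5, center_policy = c(1, 1, 1)),
               "empty particle")
  expect_error(carve_sphere(cubic_cell(2), -1), "positive")
})

test_that("carving is monotone in diameter", {
  # fixed center so the growing spheres are nested in the same lattice
  cell <- toy_unit_cells()$Fe3C
  sets <- lapply(c(4, 7, 10), function(d) {
    np <- carve_sphere(cell, d, center_policy = c(4.4, 4.4, 4.4))
    apply(round(np$positions, 6), 1, paste, collapse = ",")
  })
  expect_true(all(sets[[1]] %in% sets[[2]]))
  expect_true(all(sets[[2]] %in% sets[[3]]))
})

test_that("core/shell labelling follows the inclusive boundary rule", {
  # synthetic particle with atoms at controlled radii, R = 10, depth 4
  pos <- rbind(c(0, 0, 0), c(5.9, 0, 0), c(6.0, 0, 0), c(9.5, 0, 0))
  np <- nanoparticle(pos, rep("Fe", 4), nominal_diameter = 20,
                     center = c(0, 0, 0))
  np <- partition_core_shell(np, 4)
  expect_equal(np$region, c("core", "core", "shell", "shell"))
  # depth >= R makes everything shell
  np2 <- partition_core_shell(np, 11)
  expect_true(all(np2$region == "shell"))
  # the 7-atom particle (R = 2, depth 4) is all shell
  expect_true(all(seven_atom_particle()$region == "shell"))
  expect_error(partition_core_shell(np, -1), "non-negative")
})

test_that("region partition is always exhaustive and disjoint", {
  cell <- toy_unit_cells()$Fe2C
  for (d in c(10, 15, 22)) {
    np <- partition_core_shell(carve_sphere(cell, d), 4)
    tb <- table(factor(np$region, c("core", "shell")))
    expect_equal(sum(tb), n_atoms(np))
  }
})

test_that("XYZ export carries phase, diameter and per-atom regions", {
  np <- seven_atom_particle()
  txt <- strsplit(write_xyz(np), "\n")[[1]]
  expect_equal(as.integer(txt[1]), 7L)
  expect_match(txt[2], "phase=cubic_test")
  expect_match(txt[3], "shell$")
})
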