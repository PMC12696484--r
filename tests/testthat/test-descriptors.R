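test_that("neighbor counts match the brute-force double loop", {
  # interior atom of a large simple cubic lattice, a = 2.5
  sc <- build_supercell(cubic_cell(2.5), 5)
  counts <- neighbor_counts(list(positions = sc$positions), 3)
  brute <- brute_neighbor_counts(sc$positions, 3)
  expect_identical(counts, brute)
  center <- which.min(rowSums(sweep(sc$positions, 2,
                                    colMeans(sc$positions))^2))
  expect_equal(counts[center], 6L)
  counts4 <- neighbor_counts(list(positions = sc$positions), 4)
  expect_equal(counts4[center], 18L)  # 6 at 2.5 + 12 at 3.536
  # random gas, both cell-list and brute routes
  set.seed(11)
  pos <- matrix(runif(3 * 120, 0, 12), ncol = 3)
  expect_identical(neighbor_counts(list(positions = pos), 2.2),
                   brute_neighbor_counts(pos, 2.2))
  expect_identical(neighbor_counts(list(positions = pos[1, , drop = FALSE]),
                                   5), 0L)
})

test_that("the linked-cell pair search agrees with brute force above the
           brute-force threshold", {
  set.seed(12)
  pos <- matrix(runif(3 * 300, 0, 9), ncol = 3)
  fast <- pairs_within_cutoff(pos, 2.4, brute_max = 10L)   # force cell list
  slow <- pairs_within_cutoff(pos, 2.4, brute_max = 1000L) # force brute
  expect_equal(fast$i, slow$i)
  expect_equal(fast$j, slow$j)
  expect_equal(fast$d, slow$d, tolerance = 1e-12)
})

test_that("coordination descriptor equals the brute-force region mean", {
  np <- seven_atom_particle()
  brute <- brute_neighbor_counts(np$positions, 3)
  expect_equal(coordination_descriptor(np, 3, "all"), mean(brute))
  expect_equal(coordination_descriptor(np, 3, "all"), 36 / 7)
  # below the outer-outer spacing sqrt(8) only the six center bonds remain
  expect_equal(coordination_descriptor(np, 2.5, "all"), 12 / 7)
  # cutoff below any spacing gives exactly zero
  expect_equal(coordination_descriptor(np, 1.5, "all"), 0)
  # empty region flags missing instead of erroring
  res <- coordination_descriptor(np, 3, "core")
  expect_true(is.na(res))
  expect_match(attr(res, "missing"), "empty region")
})

test_that("coordination is monotone non-decreasing in the cutoff", {
  cell <- toy_unit_cells()$Fe5C2
  np <- partition_core_shell(carve_sphere(cell, 14), 4)
  vals <- vapply(c(3, 4, 5, 6), function(ct)
    coordination_descriptor(np, ct, "all"), 0)
  expect_true(all(diff(vals) >= 0))
})

test_that("Steinhardt q6/q4 reproduce ideal-lattice closed forms", {
  nn <- rbind(c(1, 1, 0), c(1, -1, 0), c(-1, 1, 0), c(-1, -1, 0),
              c(1, 0, 1), c(1, 0, -1), c(-1, 0, 1), c(-1, 0, -1),
              c(0, 1, 1), c(0, 1, -1), c(0, -1, 1), c(0, -1, -1))
  pos <- rbind(c(0, 0, 0), nn)
  expect_equal(per_atom_ql(pos, 6, cutoff = 1.6)[1], 0.5745,
               tolerance = 1e-4)
  expect_equal(per_atom_ql(pos, 4, cutoff = 1.6)[1], 0.19094,
               tolerance = 1e-4)
  octa <- rbind(c(0, 0, 0), c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  expect_equal(per_atom_ql(octa, 6, cutoff = 1.2)[1], 0.35355,
               tolerance = 1e-4)
  # isolated atom convention
  expect_equal(per_atom_ql(rbind(c(0, 0, 0), c(9, 9, 9)), 6, 1)[1], 0)
})

test_that("a perfect hexagon gives planar psi6 of exactly one", {
  hexagon <- t(sapply(0:5, function(k)
    c(cos(k * pi / 3), sin(k * pi / 3), 0)))
  pos <- rbind(c(0, 0, 0), hexagon)
  expect_equal(per_atom_psil(pos, 6, cutoff = 1.2)[1], 1, tolerance = 1e-12)
})

test_that("order parameters live in [0, 1] and a random gas sits well below
           the fcc value", {
  set.seed(21)
  pos <- matrix(runif(3 * 200, 0, 10), ncol = 3)
  q <- per_atom_ql(pos, 6, cutoff = 3)
  expect_true(all(q >= 0 & q <= 1))
  has_nb <- neighbor_counts(list(positions = pos), 3) >= 4
  expect_lt(mean(q[has_nb]), 0.5)
  psi <- per_atom_psil(pos, 6, cutoff = 3)
  expect_true(all(psi >= 0 & psi <= 1))
})

test_that("neighbor and order descriptors are rigid-motion invariant", {
  set.seed(31)
  cell <- toy_unit_cells()$Fe3C
  np <- partition_core_shell(carve_sphere(cell, 13), 4)
  rot <- random_rotation()
  shift <- c(5.3, -2.1, 7.7)
  np2 <- np
  np2$positions <- sweep(np$positions %*% t(rot), 2, shift, "+")
  np2$center <- as.numeric(rot %*% np$center) + shift
  expect_equal(neighbor_counts(np2, 4), neighbor_counts(np, 4))
  expect_equal(per_atom_ql(np2$positions, 6, 4), per_atom_ql(np$positions, 6, 4),
               tolerance = 1e-8)
  expect_equal(coordination_descriptor(np2, 3, "shell"),
               coordination_descriptor(np, 3, "shell"), tolerance = 1e-8)
})

test_that("pair energies match closed forms and the double-loop oracle", {
  params <- default_pair_params()
  # LJ dimer at the minimum r = 2^(1/6) sigma
  r <- 2^(1 / 6) * params$`Fe-Fe`$sigma
  e <- reference_pair_energy(rbind(c(0, 0, 0), c(r, 0, 0)), c("Fe", "Fe"))
  expect_equal(e, c(-0.2, -0.2), tolerance = 1e-12)
  expect_equal(sum(e), -params$`Fe-Fe`$epsilon, tolerance = 1e-12)
  # single atom
  expect_equal(reference_pair_energy(matrix(c(0, 0, 0), 1), "Fe"), 0)
  # three collinear equally spaced atoms: hand sum of phi(r) and phi(2r)
  phi <- function(rr, p) 4 * p$epsilon * ((p$sigma / rr)^12 - (p$sigma / rr)^6)
  d <- 2.6
  e3 <- reference_pair_energy(rbind(c(0, 0, 0), c(d, 0, 0), c(2 * d, 0, 0)),
                              rep("Fe", 3))
  hand_total <- 2 * phi(d, params$`Fe-Fe`) + phi(2 * d, params$`Fe-Fe`)
  expect_equal(sum(e3), hand_total, tolerance = 1e-12)
  # mixed-species random cluster vs brute force to 1e-10
  set.seed(41)
  pos <- matrix(runif(3 * 60, 0, 7), ncol = 3)
  spc <- sample(c("Fe", "C"), 60, replace = TRUE)
  expect_equal(reference_pair_energy(pos, spc),
               brute_lj_energy(pos, spc, params, 6), tolerance = 1e-10)
  # missing pair parameters are a configuration error
  expect_error(reference_pair_energy(rbind(c(0, 0, 0), c(2, 0, 0)),
                                     c("Fe", "Zn")), "pair")
})

test_that("energy statistics over regions reduce to simple arithmetic", {
  # constant-energy particle: difference must vanish
  fake_model <- list(per_atom_energy = function(p, s) rep(-1.5, nrow(p)),
                     bulk_energy_per_atom = function(cell) -2)
  np <- partition_core_shell(
    nanoparticle(rbind(c(0, 0, 0), c(1, 0, 0), c(4, 0, 0), c(-4, 0, 0),
                       c(0, 4, 0), c(0, -4, 0)),
                 rep("Fe", 6), nominal_diameter = 10, center = c(0, 0, 0)),
    shell_depth = 2)
  es <- energy_statistics(np, fake_model)
  expect_equal(es$diff, 0)
  # forced arithmetic: core {-2, -2}, shell {-1, -1, -1, -1}
  fake2 <- list(per_atom_energy = function(p, s)
    ifelse(sqrt(rowSums(p^2)) < 3, -2, -1))
  es2 <- energy_statistics(np, fake2)
  expect_equal(es2$avg_core, -2)
  expect_equal(es2$avg_shell, -1)
  expect_equal(es2$diff, -1)
})

test_that("lattice energy descriptors behave at the identity and surface
           limits", {
  model <- pair_potential_model()
  cell <- cubic_cell(2.9)
  np <- partition_core_shell(carve_sphere(cell, 16), 4)
  le <- lattice_energy_descriptors(np, cell, model)
  # surface atoms are under-coordinated: bulk is more negative than NP
  expect_lt(le$bulk_minus_np, 0)
  expect_lt(le$bulk_lattice_energy, le$np_lattice_energy)
  # single far-apart atom: NP lattice energy 0, difference = bulk
  np1 <- partition_core_shell(
    nanoparticle(matrix(0, 1, 3), "Fe", 2, c(0, 0, 0)), 1)
  le1 <- lattice_energy_descriptors(np1, cell, model)
  expect_equal(le1$np_lattice_energy, 0)
  expect_equal(le1$bulk_minus_np, le1$bulk_lattice_energy)
})

test_that("geometry descriptors use the nominal sphere formulas", {
  np <- partition_core_shell(
    nanoparticle(matrix(0, 1, 3), "Fe", 10, c(0, 0, 0)), 4)
  geo <- geometry_descriptors(np)
  expect_equal(geo$volume, 4 / 3 * pi * 125)
  expect_equal(geo$surface_area, 4 * pi * 25)
  expect_equal(geo$surface_to_volume, 3 / 5)
  # all-shell particle flags the core/shell ratio
  expect_true(is.na(geometry_descriptors(seven_atom_particle())$core_shell_ratio))
})

test_that("the descriptor vector has 57 bound entries with the printed ids
           in place", {
  reg <- descriptor_registry()
  expect_equal(nrow(reg), 57L)
  expect_equal(anyDuplicated(reg$id), 0L)
  cell <- toy_unit_cells()$Fe2C
  np <- partition_core_shell(carve_sphere(cell, 14), 4)
  v <- compute_descriptor_vector(np, cell)
  expect_length(v, 57L)
  expect_named(v, paste0("D", 1:57))
  # registry consistency with the direct operations
  expect_equal(unname(v["D15"]), coordination_descriptor(np, 3, "core"))
  expect_equal(unname(v["D21"]), coordination_descriptor(np, 4, "shell"))
  expect_equal(unname(v["D46"]),
               unname(bond_order_descriptor(np, l = 6, region = "all")))
  es <- energy_statistics(np, pair_potential_model())
  expect_equal(unname(v["D5"]), es$avg_core)
  expect_equal(unname(v["D7"]), es$diff)
  le <- lattice_energy_descriptors(np, cell, pair_potential_model())
  expect_equal(unname(v["D32"]), le$np_lattice_energy)
  expect_equal(unname(v["D33"]), le$bulk_minus_np)
  # determinism: bit-identical on recomputation
  expect_identical(v, compute_descriptor_vector(np, cell))
  # a wrong-size registry is a configuration error
  expect_error(compute_descriptor_vector(np, cell, registry = reg[1:56, ]),
               "57")
})

test_that("missing regions flag vector entries instead of zeroing them", {
  cell <- cubic_cell(2)
  np <- seven_atom_particle()  # all shell
  v <- compute_descriptor_vector(np, cell)
  expect_true(is.na(v["D5"]))   # core mean PE undefined
  expect_true(is.na(v["D15"]))  # core coordination undefined
  expect_true(all(c("D5", "D15") %in% attr(v, "missing")))
  expect_false(is.na(v["D6"]))  # shell quantities still present
})
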