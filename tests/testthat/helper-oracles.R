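# Independent brute-force oracles and tiny fixtures shared across tests.
# Everything here is deliberately written as plain double loops / direct
# arithmetic, independent of the package's vectorised implementations.

brute_neighbor_counts <- function(pos, cutoff) {
  n <- nrow(pos)
  counts <- integer(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && sqrt(sum((pos[i, ] - pos[j, ])^2)) <= cutoff)
        counts[i] <- counts[i] + 1L
    }
  }
  counts
}

brute_lj_energy <- function(pos, species, params, cutoff) {
  n <- nrow(pos)
  e <- numeric(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      r <- sqrt(sum((pos[i, ] - pos[j, ])^2))
      if (r > cutoff) next
      key <- paste(sort(c(species[i], species[j])), collapse = "-")
      p <- params[[key]]
      sr6 <- (p$sigma / r)^6
      e[i] <- e[i] + 0.5 * 4 * p$epsilon * (sr6^2 - sr6)
    }
  }
  e
}

brute_gt <- function(y, yhat) {
  n <- length(y)
  syy <- 0; shh <- 0; syh <- 0
  for (i in seq_len(n)) {
    syy <- syy + y[i]^2; shh <- shh + yhat[i]^2; syh <- syh + y[i] * yhat[i]
  }
  k <- syh / shh
  kp <- syh / syy
  ss <- function(v) sum((v - sum(v) / n)^2)
  r02 <- 1 - sum((y - k * yhat)^2) / ss(y)
  r02p <- 1 - sum((yhat - kp * y)^2) / ss(yhat)
  r2 <- (sum((y - mean(y)) * (yhat - mean(yhat))) /
           sqrt(ss(y) * ss(yhat)))^2
  list(k = k, k_prime = kp, r02 = r02, r02_prime = r02p, r2 = r2,
       ratio = (r2 - r02) / r2, ratio_prime = (r2 - r02p) / r2)
}

brute_apd_euclidean <- function(X, Z) {
  X <- as.matrix(X)
  n <- nrow(X)
  d <- c()
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    d <- c(d, sqrt(sum((X[i, ] - X[j, ])^2)))
  kept <- d[d < mean(d)]
  mean(kept) + Z * sd(kept)
}

brute_gower <- function(x, y, w, rng, cat_mask) {
  num <- 0; den <- 0
  for (k in seq_along(x)) {
    dk <- if (cat_mask[k]) as.numeric(x[[k]] != y[[k]]) else
      min(1, abs(as.numeric(x[[k]]) - as.numeric(y[[k]])) / rng[k])
    num <- num + w[k] * dk
    den <- den + w[k]
  }
  num / den
}

cubic_cell <- function(a = 2) {
  unit_cell(lattice_from_parameters(a, a, a),
            data.frame(species = "Fe", fx = 0, fy = 0, fz = 0),
            phase_id = "cubic_test")
}

# central atom plus its six face neighbors of a simple cubic a = 2 lattice
seven_atom_particle <- function() {
  np <- carve_sphere(cubic_cell(2), diameter = 4, center_policy = "atom")
  partition_core_shell(np, shell_depth = 4)
}

random_rotation <- function() {
  qr.Q(qr(matrix(rnorm(9), 3, 3)))
}

# small scenario for fast pipeline-level unit tests (not the study scenario)
small_scenario <- function(seed = 3L) {
  sim_scenario(
    n_rows = 84,
    particles = expand.grid(phase = c("Fe2C", "Fe5C2"),
                            diameter_nm = c(4.9, 6.2),
                            stringsAsFactors = FALSE),
    seed = seed)
}

minimal_cif <- paste(
  "data_min",
  "_cell_length_a 2",
  "_cell_length_b 2",
  "_cell_length_c 2",
  "loop_",
  "_atom_site_label",
  "_atom_site_fract_x",
  "_atom_site_fract_y",
  "_atom_site_fract_z",
  "Fe1 0 0 0",
  sep = "\n")
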