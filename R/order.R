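#' Bond-orientational (hexatic) order parameters
#'
#' Steinhardt rotational invariants
#' `q_l(i) = sqrt( 4*pi/(2l+1) * sum_m | <Y_lm(r_ij)>_j |^2 )` averaged over
#' the neighbors j of atom i within a cutoff, and the planar variant
#' `psi_l(i) = | <exp(i l theta_ij)>_j |` with `theta_ij` the bond angle in
#' the xy-plane. Both lie in `[0, 1]`; an atom with no neighbor contributes 0.
#'
#' `per_atom_ql()` and `per_atom_psil()` return the per-atom values;
#' [bond_order_descriptor()] averages them over a region.
#'
#' @param positions n x 3 Cartesian matrix (Angstrom).
#' @param l harmonic order (positive integer; l = 6 is the "second hexatic"
#'   order used throughout, l = 4 its companion).
#' @param cutoff neighbor cutoff (Angstrom), default 4.
#' @param pairs optional precomputed [pairs_within_cutoff()] result.
#' @return numeric vector of length n in `[0, 1]`.
#' @export
per_atom_ql <- function(positions, l, cutoff = 4, pairs = NULL) {
  stopif(l < 1, "harmonic order l must be >= 1")
  positions <- as.matrix(positions)
  n <- nrow(positions)
  if (is.null(pairs)) pairs <- pairs_within_cutoff(positions, cutoff)
  if (nrow(pairs) == 0L) return(numeric(n))

  # directed bonds: i -> j and j -> i
  from <- c(pairs$i, pairs$j)
  to <- c(pairs$j, pairs$i)
  v <- positions[to, , drop = FALSE] - positions[from, , drop = FALSE]
  r <- sqrt(rowSums(v^2))
  cos_th <- pmin(1, pmax(-1, v[, 3] / r))
  phi <- atan2(v[, 2], v[, 1])

  # associated Legendre P_l^m(cos theta) for m = 0..l (Condon-Shortley),
  # rows of pracma::legendre
  P <- pracma::legendre(l, cos_th)
  if (is.null(dim(P))) P <- matrix(P, ncol = 1)  # single bond

  nb <- tabulate(from, nbins = n)
  acc <- numeric(n)
  for (m in 0:l) {
    Nlm <- sqrt((2 * l + 1) / (4 * pi) *
                  exp(lgamma(l - m + 1) - lgamma(l + m + 1)))
    ylm_re <- Nlm * P[m + 1, ] * cos(m * phi)
    ylm_im <- Nlm * P[m + 1, ] * sin(m * phi)
    s_re <- rowsum(ylm_re, from, reorder = FALSE)
    s_im <- rowsum(ylm_im, from, reorder = FALSE)
    idx <- as.integer(rownames(s_re))
    mag2 <- numeric(n)
    mag2[idx] <- (s_re^2 + s_im^2)
    mag2[nb > 0] <- mag2[nb > 0] / nb[nb > 0]^2   # |mean Y_lm|^2
    acc <- acc + if (m == 0) mag2 else 2 * mag2   # +/- m magnitudes equal
  }
  q <- sqrt(4 * pi / (2 * l + 1) * acc)
  q[nb == 0] <- 0
  pmin(q, 1)
}

#' @rdname per_atom_ql
#' @export
per_atom_psil <- function(positions, l, cutoff = 4, pairs = NULL) {
  stopif(l < 1, "harmonic order l must be >= 1")
  positions <- as.matrix(positions)
  n <- nrow(positions)
  if (is.null(pairs)) pairs <- pairs_within_cutoff(positions, cutoff)
  if (nrow(pairs) == 0L) return(numeric(n))
  from <- c(pairs$i, pairs$j)
  to <- c(pairs$j, pairs$i)
  v <- positions[to, , drop = FALSE] - positions[from, , drop = FALSE]
  th <- atan2(v[, 2], v[, 1])
  nb <- tabulate(from, nbins = n)
  s_re <- rowsum(cos(l * th), from, reorder = FALSE)
  s_im <- rowsum(sin(l * th), from, reorder = FALSE)
  idx <- as.integer(rownames(s_re))
  out <- numeric(n)
  out[idx] <- sqrt(s_re^2 + s_im^2)
  out[nb > 0] <- out[nb > 0] / nb[nb > 0]
  out[nb == 0] <- 0
  pmin(out, 1)
}
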