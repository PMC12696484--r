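#' Pairs of atoms within a cutoff
#'
#' Returns every unordered pair `(i, j)`, `i < j`, with
#' `||r_i - r_j|| <= cutoff` (inclusive boundary). A linked-cell search is
#' used above `brute_max` atoms; both routes give identical pairs.
#'
#' @param positions n x 3 Cartesian matrix (Angstrom).
#' @param cutoff neighbor cutoff (Angstrom), must be positive.
#' @param brute_max below this atom count a direct pairwise search is used.
#' @return data.frame with integer columns `i`, `j` and numeric `d`.
#' @export
pairs_within_cutoff <- function(positions, cutoff, brute_max = 800L) {
  stopif(cutoff <= 0, "cutoff must be positive")
  positions <- as.matrix(positions)
  n <- nrow(positions)
  if (n < 2L) return(data.frame(i = integer(), j = integer(), d = numeric()))

  if (n <= brute_max) {
    d <- as.matrix(stats::dist(positions))
    idx <- which(upper.tri(d) & d <= cutoff, arr.ind = TRUE)
    return(data.frame(i = idx[, 1], j = idx[, 2],
                      d = d[idx])[order(idx[, 1], idx[, 2]), ])
  }

  # linked cells: bin side = cutoff, compare each cell with itself and the
  # 13 half-neighborhood offsets so each pair is visited once
  bins <- floor(sweep(positions, 2, apply(positions, 2, min)) / cutoff)
  nb <- apply(bins, 2, max) + 1L
  key <- bins[, 1] + nb[1] * (bins[, 2] + nb[2] * bins[, 3])
  groups <- split(seq_len(n), key)
  offsets <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offsets <- offsets[offsets[, 3] > 0 |
                       (offsets[, 3] == 0 & offsets[, 2] > 0) |
                       (offsets[, 3] == 0 & offsets[, 2] == 0 &
                          offsets[, 1] >= 0), , drop = FALSE]
  out_i <- list(); out_j <- list(); out_d <- list(); k <- 0L
  keys <- as.numeric(names(groups))
  kz <- floor(keys / (nb[1] * nb[2]))
  ky <- floor((keys - kz * nb[1] * nb[2]) / nb[1])
  kx <- keys - nb[1] * (ky + nb[2] * kz)
  keymap <- stats::setNames(seq_along(groups), names(groups))
  for (g in seq_along(groups)) {
    a <- groups[[g]]
    for (o in seq_len(nrow(offsets))) {
      cx <- kx[g] + offsets[o, 1]; cy <- ky[g] + offsets[o, 2]
      cz <- kz[g] + offsets[o, 3]
      if (cx < 0 || cy < 0 || cz < 0 || cx >= nb[1] || cy >= nb[2] ||
          cz >= nb[3]) next
      tkey <- as.character(cx + nb[1] * (cy + nb[2] * cz))
      tg <- keymap[tkey]
      if (is.na(tg)) next
      b <- groups[[tg]]
      same <- tg == g
      if (same && length(a) < 2L) next
      dx <- outer(positions[a, 1], positions[b, 1], "-")
      dy <- outer(positions[a, 2], positions[b, 2], "-")
      dz <- outer(positions[a, 3], positions[b, 3], "-")
      dd <- sqrt(dx^2 + dy^2 + dz^2)
      if (same) {
        sel <- which(upper.tri(dd) & dd <= cutoff, arr.ind = TRUE)
      } else {
        sel <- which(dd <= cutoff, arr.ind = TRUE)
      }
      if (nrow(sel) == 0L) next
      k <- k + 1L
      ii <- a[sel[, 1]]; jj <- b[sel[, 2]]
      swap <- ii > jj
      tmp <- ii[swap]; ii[swap] <- jj[swap]; jj[swap] <- tmp
      out_i[[k]] <- ii; out_j[[k]] <- jj
      out_d[[k]] <- dd[sel]
    }
  }
  if (k == 0L) return(data.frame(i = integer(), j = integer(), d = numeric()))
  res <- data.frame(i = unlist(out_i), j = unlist(out_j), d = unlist(out_d))
  res[order(res$i, res$j), ]
}

#' Per-atom neighbor counts
#'
#' `count_i = |{j != i : ||r_i - r_j|| <= cutoff}|`; equals a brute-force
#' double loop on any input. A single atom has count 0.
#'
#' @param np a [nanoparticle()] (or any object with a `positions` matrix).
#' @param cutoff neighbor cutoff (Angstrom).
#' @return integer vector of length n.
#' @export
neighbor_counts <- function(np, cutoff) {
  pos <- if (is.matrix(np)) np else np$positions
  n <- nrow(pos)
  pr <- pairs_within_cutoff(pos, cutoff)
  counts <- tabulate(c(pr$i, pr$j), nbins = n)
  as.integer(counts)
}
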