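#' Crystal unit cells from CIF documents
#'
#' A `unit_cell` holds the Cartesian lattice vectors (rows of a 3x3 matrix,
#' in Angstrom, with the crystallographic convention a along x and b in the
#' xy-plane), the symmetry-expanded fractional sites, and a phase label.
#' The supported CIF dialect covers cell parameters, space-group /
#' symmetry-equivalent operator loops and fractional `atom_site` loops;
#' anisotropic displacement and charge tags are ignored.
#'
#' @param lattice 3x3 numeric matrix, rows are the a, b, c vectors (Angstrom).
#' @param sites data.frame with columns `species`, `fx`, `fy`, `fz`
#'   (fractional coordinates, wrapped into `[0, 1)`).
#' @param phase_id character phase label, e.g. `"Fe3C"`.
#' @return An object of class `unit_cell`.
#' @export
unit_cell <- function(lattice, sites, phase_id = "unknown") {
  lattice <- matrix(as.numeric(lattice), 3, 3)
  stopif(any(!is.finite(lattice)), "lattice vectors must be finite")
  vol <- abs(det(lattice))
  stopif(vol <= 1e-9, "unit cell volume must be positive (degenerate lattice)")
  stopif(!is.data.frame(sites) || nrow(sites) < 1L,
         "unit cell needs at least one site")
  stopif(!all(c("species", "fx", "fy", "fz") %in% names(sites)),
         "sites must have columns species, fx, fy, fz")
  frac <- as.matrix(sites[, c("fx", "fy", "fz")])
  frac <- frac - floor(frac)  # wrap into [0, 1)
  sites$fx <- frac[, 1]; sites$fy <- frac[, 2]; sites$fz <- frac[, 3]
  structure(
    list(lattice = lattice, sites = sites, phase_id = as.character(phase_id)),
    class = "unit_cell"
  )
}

#' @export
print.unit_cell <- function(x, ...) {
  cat("<unit_cell> phase:", x$phase_id, "\n")
  cat("  volume:", format(cell_volume(x), digits = 6), "A^3;",
      nrow(x$sites), "site(s):",
      paste(unique(x$sites$species), collapse = ", "), "\n")
  invisible(x)
}

#' Cell volume in cubic Angstrom
#' @param cell a [unit_cell()].
#' @export
cell_volume <- function(cell) abs(det(cell$lattice))

#' Cartesian lattice vectors from cell parameters
#'
#' Standard crystallographic convention: a along x, b in the xy-plane.
#'
#' @param a,b,c cell lengths (Angstrom).
#' @param alpha,beta,gamma cell angles (degrees).
#' @return 3x3 matrix, rows are the lattice vectors.
#' @export
lattice_from_parameters <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  stopif(any(c(a, b, c) <= 0), "cell lengths must be positive")
  ar <- alpha * pi / 180; br <- beta * pi / 180; gr <- gamma * pi / 180
  av <- c(a, 0, 0)
  bv <- c(b * cos(gr), b * sin(gr), 0)
  cx <- c * cos(br)
  cy <- c * (cos(ar) - cos(br) * cos(gr)) / sin(gr)
  cz2 <- c^2 - cx^2 - cy^2
  stopif(cz2 <= 0, "cell angles do not define a positive-volume lattice")
  rbind(av, bv, c(cx, cy, sqrt(cz2)), deparse.level = 0)
}

# Parse one symmetry operator string like "-x, y+1/2, 1/2-z" into a function
# mapping fractional coordinates. Only x, y, z, digits, + - / . and commas
# are allowed; evaluation happens in a sealed environment.
parse_symop <- function(op) {
  op <- gsub("['\"]", "", tolower(op))
  parts <- strsplit(op, ",")[[1]]
  stopif(length(parts) != 3L, "malformed symmetry operator: ", op)
  stopif(grepl("[^xyz0-9+*/. -]", paste(parts, collapse = "")),
         "unsupported token in symmetry operator: ", op)
  exprs <- lapply(parts, function(p) parse(text = p)[[1]])
  function(frac) {
    env <- new.env(parent = baseenv())
    assign("x", frac[1], env); assign("y", frac[2], env); assign("z", frac[3], env)
    vapply(exprs, eval, numeric(1), envir = env)
  }
}

# Strip oxidation-state suffixes: "Fe3+" -> "Fe", "C0+" -> "C".
normalize_species <- function(s) {
  m <- regmatches(s, regexpr("^[A-Za-z]{1,2}", s))
  ifelse(nchar(m) > 0, paste0(toupper(substr(m, 1, 1)),
                              tolower(substr(m, 2, 2))), s)
}

cif_numeric <- function(x) {
  # CIF numbers may carry an "(esd)" suffix: 4.526(3)
  as.numeric(sub("\\(.*\\)$", "", x))
}

#' Parse a CIF document into a unit cell
#'
#' Reads cell parameters, symmetry operators (`_symmetry_equiv_pos_as_xyz`
#' or `_space_group_symop_operation_xyz`; P1 assumed when absent) and the
#' fractional `atom_site` loop, applies all operators and merges duplicate
#' images closer than `merge_tol` Angstrom.
#'
#' @param text CIF document as a single string, character vector of lines,
#'   or a path to a `.cif` file.
#' @param phase_id optional phase label; defaults to the CIF `data_` block
#'   name or chemical formula when present.
#' @param merge_tol Cartesian merge tolerance for symmetry-duplicate sites
#'   (Angstrom).
#' @return A [unit_cell()].
#' @export
parse_cif <- function(text, phase_id = NULL, merge_tol = 0.01) {
  if (length(text) == 1L && !grepl("\n", text) && file.exists(text))
    text <- readLines(text, warn = FALSE)
  if (length(text) == 1L) text <- strsplit(text, "\n")[[1]]
  lines <- trimws(text)
  lines <- lines[!grepl("^#", lines)]

  get_tag <- function(tag) {
    hit <- grep(paste0("^", tag, "\\b"), lines, value = TRUE)
    if (length(hit) == 0L) return(NULL)
    val <- trimws(sub(paste0("^", tag, "\\s*"), "", hit[1]))
    if (nchar(val) == 0L) NULL else val
  }

  need <- function(tag) {
    v <- get_tag(tag)
    stopif(is.null(v), "CIF parse error: missing required tag ", tag)
    v
  }

  a <- cif_numeric(need("_cell_length_a"))
  b <- cif_numeric(need("_cell_length_b"))
  cc <- cif_numeric(need("_cell_length_c"))
  al <- cif_numeric(get_tag("_cell_angle_alpha") %||% "90")
  be <- cif_numeric(get_tag("_cell_angle_beta") %||% "90")
  ga <- cif_numeric(get_tag("_cell_angle_gamma") %||% "90")
  lattice <- lattice_from_parameters(a, b, cc, al, be, ga)

  # ---- loops ------------------------------------------------------------
  loop_starts <- grep("^loop_", lines)
  read_loop <- function(start) {
    i <- start + 1L
    headers <- character()
    while (i <= length(lines) && grepl("^_", lines[i])) {
      headers <- c(headers, strsplit(lines[i], "\\s+")[[1]][1])
      i <- i + 1L
    }
    rows <- list()
    while (i <= length(lines) && nchar(lines[i]) > 0L &&
           !grepl("^(_|loop_|data_)", lines[i])) {
      rows[[length(rows) + 1L]] <- lines[i]
      i <- i + 1L
    }
    list(headers = headers, rows = rows)
  }
  loops <- lapply(loop_starts, read_loop)

  # symmetry operators
  ops <- character()
  for (lp in loops) {
    if (any(grepl("_symmetry_equiv_pos_as_xyz|_space_group_symop_operation_xyz",
                  lp$headers))) {
      col <- grep("as_xyz|operation_xyz", lp$headers)
      for (r in lp$rows) {
        # operator may be quoted with internal spaces; treat whole row minus
        # a possible leading index as the operator
        row <- sub("^\\s*\\d+\\s+", "", r)
        row <- gsub("['\"]", "", row)
        if (length(col) && grepl("[xyz]", row)) ops <- c(ops, row)
      }
    }
  }
  if (length(ops) == 0L) ops <- "x, y, z"

  # atom sites
  site_loop <- NULL
  for (lp in loops) {
    if (any(grepl("_atom_site_fract_x", lp$headers))) { site_loop <- lp; break }
  }
  stopif(is.null(site_loop), "CIF parse error: missing _atom_site loop")
  h <- site_loop$headers
  ix <- match("_atom_site_fract_x", h)
  iy <- match("_atom_site_fract_y", h)
  iz <- match("_atom_site_fract_z", h)
  isp <- match("_atom_site_type_symbol", h)
  if (is.na(isp)) isp <- match("_atom_site_label", h)
  stopif(any(is.na(c(ix, iy, iz, isp))),
         "CIF parse error: incomplete _atom_site loop (need label/type and fract_x/y/z)")
  fields <- lapply(site_loop$rows, function(r) strsplit(r, "\\s+")[[1]])
  fields <- fields[vapply(fields, length, 1L) >= max(ix, iy, iz, isp)]
  stopif(length(fields) == 0L, "CIF parse error: empty _atom_site loop")
  base <- data.frame(
    species = normalize_species(vapply(fields, `[`, "", isp)),
    fx = vapply(fields, function(f) cif_numeric(f[ix]), 0),
    fy = vapply(fields, function(f) cif_numeric(f[iy]), 0),
    fz = vapply(fields, function(f) cif_numeric(f[iz]), 0),
    stringsAsFactors = FALSE
  )

  # apply symmetry, wrap, merge duplicates (Cartesian tolerance, periodic)
  op_funs <- lapply(ops, parse_symop)
  expanded <- do.call(rbind, lapply(seq_len(nrow(base)), function(i) {
    frac <- as.numeric(base[i, c("fx", "fy", "fz")])
    pts <- t(vapply(op_funs, function(f) f(frac), numeric(3)))
    data.frame(species = base$species[i], fx = pts[, 1], fy = pts[, 2],
               fz = pts[, 3], stringsAsFactors = FALSE)
  }))
  frac <- as.matrix(expanded[, c("fx", "fy", "fz")])
  frac <- frac - floor(frac)
  keep <- rep(TRUE, nrow(frac))
  for (i in seq_len(nrow(frac))) {
    if (!keep[i]) next
    if (i == nrow(frac)) break
    later <- (i + 1L):nrow(frac)
    d <- frac[later, , drop = FALSE] -
      matrix(frac[i, ], length(later), 3, byrow = TRUE)
    d <- d - round(d)                       # minimal image in fractional space
    cart <- d %*% lattice
    dup <- sqrt(rowSums(cart^2)) < merge_tol &
      expanded$species[later] == expanded$species[i]
    keep[later][dup] <- FALSE
  }
  merged <- data.frame(species = expanded$species[keep],
                       fx = frac[keep, 1], fy = frac[keep, 2],
                       fz = frac[keep, 3], stringsAsFactors = FALSE)

  if (is.null(phase_id)) {
    blk <- grep("^data_", lines, value = TRUE)
    phase_id <- if (length(blk)) sub("^data_", "", blk[1]) else "unknown"
  }
  unit_cell(lattice, merged, phase_id)
}

#' Write a unit cell as a P1 CIF document
#'
#' Inverse of [parse_cif()] for round-trip checks; symmetry is expanded, so
#' the output is always P1.
#'
#' @param cell a [unit_cell()].
#' @param path optional output file; when `NULL` the text is returned.
#' @export
write_cif <- function(cell, path = NULL) {
  lat <- cell$lattice
  a <- sqrt(sum(lat[1, ]^2)); b <- sqrt(sum(lat[2, ]^2)); cc <- sqrt(sum(lat[3, ]^2))
  ang <- function(u, v) acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2))) * 180 / pi
  lines <- c(
    paste0("data_", gsub("\\s", "_", cell$phase_id)),
    sprintf("_cell_length_a %.10f", a),
    sprintf("_cell_length_b %.10f", b),
    sprintf("_cell_length_c %.10f", cc),
    sprintf("_cell_angle_alpha %.10f", ang(lat[2, ], lat[3, ])),
    sprintf("_cell_angle_beta %.10f", ang(lat[1, ], lat[3, ])),
    sprintf("_cell_angle_gamma %.10f", ang(lat[1, ], lat[2, ])),
    "loop_",
    "_symmetry_equiv_pos_as_xyz",
    "'x, y, z'",
    "loop_",
    "_atom_site_label",
    "_atom_site_type_symbol",
    "_atom_site_fract_x",
    "_atom_site_fract_y",
    "_atom_site_fract_z",
    sprintf("%s%d %s %.10f %.10f %.10f",
            cell$sites$species, seq_len(nrow(cell$sites)), cell$sites$species,
            cell$sites$fx, cell$sites$fy, cell$sites$fz)
  )
  if (is.null(path)) return(paste(lines, collapse = "\n"))
  writeLines(lines, path)
  invisible(path)
}
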