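#' Create a lattice from three row vectors
#'
#' @param cell 3x3 numeric matrix whose rows are the lattice vectors a, b, c
#'   in Angstrom. Must be right-handed (positive determinant).
#' @return An object of class `csp_lattice` (the validated matrix).
#' @examples
#' lat <- lattice(diag(3) * 10)
#' lattice_params(lat)
#' @export
lattice <- function(cell) {
  cell <- as.matrix(cell)
  stopifnot(all(dim(cell) == c(3, 3)), all(is.finite(cell)))
  if (det(cell) <= 0) {
    stop("lattice must be right-handed: det(cell) > 0, got ", det(cell))
  }
  structure(cell, class = "csp_lattice")
}

#' @export
as.matrix.csp_lattice <- function(x, ...) {
  attr(x, "class") <- NULL
  x
}

#' @rdname lattice
#' @param lat A `csp_lattice`.
#' @return `lattice_params()`: named vector (a, b, c, alpha, beta, gamma)
#'   with lengths in Angstrom and angles in degrees.
#' @export
lattice_params <- function(lat) {
  a <- lat[1, ]; b <- lat[2, ]; c_ <- lat[3, ]
  len <- c(sqrt(sum(a^2)), sqrt(sum(b^2)), sqrt(sum(c_^2)))
  ang <- function(u, v) acos(max(-1, min(1, sum(u * v) / sqrt(sum(u^2) * sum(v^2))))) * 180 / pi
  c(a = len[1], b = len[2], c = len[3],
    alpha = ang(b, c_), beta = ang(a, c_), gamma = ang(a, b))
}

#' @rdname lattice
#' @param params Named or positional vector (a, b, c, alpha, beta, gamma),
#'   Angstrom / degrees.
#' @export
lattice_from_params <- function(params) {
  p <- as.numeric(params)
  a <- p[1]; b <- p[2]; cc <- p[3]
  al <- p[4] * pi / 180; be <- p[5] * pi / 180; ga <- p[6] * pi / 180
  # standard crystallographic construction: a along x, b in xy plane
  v1 <- c(a, 0, 0)
  v2 <- c(b * cos(ga), b * sin(ga), 0)
  cx <- cc * cos(be)
  cy <- cc * (cos(al) - cos(be) * cos(ga)) / sin(ga)
  cz2 <- cc^2 - cx^2 - cy^2
  if (cz2 <= 0) stop("inconsistent cell parameters (no real cell)")
  lattice(rbind(v1, v2, c(cx, cy, sqrt(cz2))))
}

#' Volume of a lattice in cubic Angstrom
#' @param lat A `csp_lattice` or 3x3 cell matrix.
#' @export
cell_volume <- function(lat) abs(det(as.matrix(lat)))

#' Convert coordinates between fractional and Cartesian
#'
#' Fractional coordinates are row vectors in the basis of the lattice rows:
#' `cart = frac %*% cell`.
#'
#' @param lat A `csp_lattice`.
#' @param coords Nx3 matrix (or length-3 vector) of coordinates.
#' @param direction `"frac_to_cart"` or `"cart_to_frac"`.
#' @return Nx3 matrix of converted coordinates.
#' @export
coords_convert <- function(lat, coords, direction = c("frac_to_cart", "cart_to_frac")) {
  direction <- match.arg(direction)
  cm <- as.matrix(lat)
  if (abs(det(cm)) < 1e-300) stop("singular cell")
  x <- matrix(as.numeric(coords), ncol = 3)
  if (!all(is.finite(x))) stop("non-finite coordinates")
  if (direction == "frac_to_cart") x %*% cm else x %*% solve(cm)
}

# number of periodic images needed per axis to cover `cutoff`
image_bounds <- function(cell, cutoff) {
  v <- abs(det(cell))
  cross <- function(u, w) c(u[2] * w[3] - u[3] * w[2],
                            u[3] * w[1] - u[1] * w[3],
                            u[1] * w[2] - u[2] * w[1])
  d <- c(v / sqrt(sum(cross(cell[2, ], cell[3, ])^2)),
         v / sqrt(sum(cross(cell[3, ], cell[1, ])^2)),
         v / sqrt(sum(cross(cell[1, ], cell[2, ])^2)))
  pmax(1L, as.integer(ceiling(cutoff / d)))
}

# all integer translations -n..n per axis as an M x 3 matrix
image_shifts <- function(n) {
  as.matrix(expand.grid(-n[1]:n[1], -n[2]:n[2], -n[3]:n[3]))
}

#' Minimum-image distance between two fractional points
#'
#' Distance minimised over periodic images; correct for skewed cells (the
#' search range is widened until it provably brackets the minimum).
#'
#' @param lat A `csp_lattice`.
#' @param p1,p2 Fractional coordinates (length 3).
#' @return Distance in Angstrom.
#' @export
min_image_distance <- function(lat, p1, p2) {
  cm <- as.matrix(lat)
  d <- (as.numeric(p2) - as.numeric(p1)) %% 1
  d <- d - round(d)                       # into [-0.5, 0.5)
  base <- sqrt(sum((d %*% cm)^2))
  n <- image_bounds(cm, base + 1e-9)
  sh <- image_shifts(n)
  dd <- sh + matrix(d, nrow(sh), 3, byrow = TRUE)
  min(sqrt(rowSums((dd %*% cm)^2)))
}

# vectorised minimum-image displacement vectors (cartesian) for many pairs:
# dfrac is an N x 3 matrix of fractional differences; returns N x 3 cartesian
# displacements of the nearest image (adequate for cells close to reduced form;
# exact code paths use image enumeration instead).
min_image_cart <- function(cell, dfrac) {
  d <- dfrac %% 1
  d <- d - round(d)
  d %*% cell
}

#' Construct a molecule
#'
#' @param symbols Character vector of element symbols.
#' @param positions Nx3 Cartesian coordinates (Angstrom).
#' @param bonds Two-column integer matrix of 1-based atom index pairs
#'   (optional; detected by [detect_bonds()] if `NULL`).
#' @param formal_charge Integer total charge in e.
#' @return Object of class `csp_molecule` with element data attached.
#' @export
molecule <- function(symbols, positions, bonds = NULL, formal_charge = 0L) {
  positions <- matrix(as.numeric(positions), ncol = 3)
  stopifnot(length(symbols) == nrow(positions))
  el <- element_spec(symbols)
  if (is.null(bonds)) bonds <- detect_bonds(symbols, positions)
  if (length(bonds) > 0) {
    bonds <- matrix(as.integer(bonds), ncol = 2)
    if (any(bonds < 1 | bonds > length(symbols))) stop("bond indices out of range")
  } else {
    bonds <- matrix(integer(0), ncol = 2)
  }
  structure(list(symbols = symbols, positions = positions, bonds = bonds,
                 elements = el, formal_charge = as.integer(formal_charge)),
            class = "csp_molecule")
}

#' @rdname molecule
#' @param bond_scale Bond detection scale on summed covalent radii.
#' @export
detect_bonds <- function(symbols, positions, bond_scale = 1.2) {
  n <- length(symbols)
  if (n < 2) return(matrix(integer(0), ncol = 2))
  rc <- element_spec(symbols)$r_cov
  out <- list()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- sqrt(sum((positions[i, ] - positions[j, ])^2))
    if (d <= bond_scale * (rc[i] + rc[j])) out[[length(out) + 1]] <- c(i, j)
  }
  if (length(out) == 0) matrix(integer(0), ncol = 2) else do.call(rbind, out)
}

#' Construct a periodic crystal structure
#'
#' @param lat A `csp_lattice` (or 3x3 cell matrix).
#' @param species Character vector of element symbols, one per site.
#' @param frac_coords Nx3 fractional coordinates; wrapped into `[0, 1)`.
#' @param Z Molecules per unit cell (>= 1).
#' @param space_group Space-group number 1-230, or `NA` if unknown.
#' @param molecule_of_site Optional integer molecule id per site (1-based).
#' @param charges Optional per-site point charges (e); default 0.
#' @param total_charge Integer net cell charge (e).
#' @return Object of class `csp_crystal`.
#' @export
crystal_structure <- function(lat, species, frac_coords, Z = 1L,
                              space_group = NA_integer_,
                              molecule_of_site = NULL, charges = NULL,
                              total_charge = 0L) {
  if (!inherits(lat, "csp_lattice")) lat <- lattice(lat)
  frac_coords <- matrix(as.numeric(frac_coords), ncol = 3) %% 1
  stopifnot(length(species) == nrow(frac_coords), Z >= 1)
  el <- element_spec(species)
  if (!is.null(molecule_of_site)) {
    stopifnot(length(molecule_of_site) == length(species))
    ids <- sort(unique(molecule_of_site))
    if (!identical(as.integer(ids), seq_along(ids))) {
      stop("molecule ids must partition sites as 1..m")
    }
  }
  if (is.null(charges)) charges <- rep(0, length(species))
  stopifnot(length(charges) == length(species))
  structure(list(lattice = lat, species = species, frac_coords = frac_coords,
                 elements = el, Z = as.integer(Z),
                 space_group = as.integer(space_group),
                 molecule_of_site = molecule_of_site,
                 charges = as.numeric(charges),
                 total_charge = as.integer(total_charge)),
            class = "csp_crystal")
}

#' @export
print.csp_crystal <- function(x, ...) {
  p <- lattice_params(x$lattice)
  cat(sprintf("<csp_crystal> %d sites, Z = %d, V = %.3f A^3\n",
              length(x$species), x$Z, cell_volume(x$lattice)))
  cat(sprintf("  a=%.4f b=%.4f c=%.4f alpha=%.2f beta=%.2f gamma=%.2f\n",
              p[1], p[2], p[3], p[4], p[5], p[6]))
  if (!is.na(x$space_group)) cat("  space group #", x$space_group, "\n", sep = "")
  invisible(x)
}

#' @export
print.csp_molecule <- function(x, ...) {
  cat(sprintf("<csp_molecule> %s (%d atoms, %d bonds, charge %+d)\n",
              paste(x$symbols, collapse = ""), length(x$symbols),
              nrow(x$bonds), x$formal_charge))
  invisible(x)
}

#' Construct an n-mer (finite cluster of whole molecules)
#'
#' @param molecules List of `csp_molecule` (order n = 1-8).
#' @param total_charge Integer net charge (e); defaults to the sum of the
#'   members' formal charges.
#' @return Object of class `csp_nmer`.
#' @export
nmer <- function(molecules, total_charge = NULL) {
  stopifnot(length(molecules) >= 1, length(molecules) <= 8,
            all(vapply(molecules, inherits, TRUE, "csp_molecule")))
  if (is.null(total_charge)) {
    total_charge <- sum(vapply(molecules, function(m) m$formal_charge, 0L))
  }
  structure(list(molecules = molecules, order = length(molecules),
                 total_charge = as.integer(total_charge)),
            class = "csp_nmer")
}

# flatten an nmer / molecule to (symbols, positions, molecule ids, bonds)
as_atoms <- function(x) {
  if (inherits(x, "csp_molecule")) {
    list(symbols = x$symbols, positions = x$positions,
         mol_id = rep(1L, length(x$symbols)), bonds = x$bonds)
  } else if (inherits(x, "csp_nmer")) {
    bonds <- NULL; offset <- 0L
    for (m in x$molecules) {
      if (nrow(m$bonds) > 0) bonds <- rbind(bonds, m$bonds + offset)
      offset <- offset + length(m$symbols)
    }
    if (is.null(bonds)) bonds <- matrix(integer(0), ncol = 2)
    list(symbols = unlist(lapply(x$molecules, function(m) m$symbols)),
         positions = do.call(rbind, lapply(x$molecules, function(m) m$positions)),
         mol_id = rep(seq_along(x$molecules),
                      vapply(x$molecules, function(m) length(m$symbols), 0L)),
         bonds = bonds)
  } else if (inherits(x, "csp_crystal")) {
    list(symbols = x$species,
         positions = coords_convert(x$lattice, x$frac_coords, "frac_to_cart"),
         mol_id = x$molecule_of_site,
         bonds = matrix(integer(0), ncol = 2))
  } else stop("unsupported geometry type")
}

#' Partition crystal sites into molecules by covalent connectivity
#'
#' Sites i, j are bonded iff their minimum-image distance does not exceed
#' `bond_scale * (r_cov_i + r_cov_j)`; molecules are the connected components,
#' honouring bonds across periodic boundaries.
#'
#' @param crystal A `csp_crystal`.
#' @param bond_scale Dimensionless scale on summed covalent radii (default 1.2).
#' @return The crystal with `molecule_of_site` filled (ids 1..m, in order of
#'   first appearance) and attribute `"bond_images"` storing, per bond, the
#'   integer image shift of site j relative to site i.
#' @export
identify_molecules <- function(crystal, bond_scale = 1.2) {
  n <- length(crystal$species)
  cell <- as.matrix(crystal$lattice)
  rc <- crystal$elements$r_cov
  maxbond <- bond_scale * 2 * max(rc)
  nb <- image_bounds(cell, maxbond)
  sh <- image_shifts(nb)
  shc <- sh %*% cell
  adj <- vector("list", n)
  bond_shift <- list()
  if (bond_scale > 0 && n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        df <- crystal$frac_coords[j, ] - crystal$frac_coords[i, ]
        dc <- matrix(df %*% cell, nrow(shc), 3, byrow = TRUE) + shc
        dists <- sqrt(rowSums(dc^2))
        k <- which.min(dists)
        if (dists[k] <= bond_scale * (rc[i] + rc[j])) {
          adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
          bond_shift[[length(bond_shift) + 1]] <-
            list(i = i, j = j, shift = as.numeric(sh[k, ]))
        }
      }
    }
  }
  # connected components by BFS
  mol <- rep(NA_integer_, n)
  nextid <- 0L
  for (s in seq_len(n)) {
    if (!is.na(mol[s])) next
    nextid <- nextid + 1L
    queue <- s; mol[s] <- nextid
    while (length(queue) > 0) {
      v <- queue[[1]]; queue <- queue[-1]
      for (w in adj[[v]]) if (is.na(mol[w])) { mol[w] <- nextid; queue <- c(queue, w) }
    }
  }
  crystal$molecule_of_site <- mol
  attr(crystal, "bond_images") <- bond_shift
  crystal
}

# unwrap every molecule of a partitioned crystal: returns a list of
# csp_molecule in cartesian coordinates with no bond crossing an image
# boundary, plus per-molecule site indices and fractional (unwrapped) coords.
unwrap_molecules <- function(crystal, bond_scale = 1.2) {
  if (is.null(crystal$molecule_of_site) || is.null(attr(crystal, "bond_images"))) {
    crystal <- identify_molecules(crystal, bond_scale)
  }
  n <- length(crystal$species)
  cell <- as.matrix(crystal$lattice)
  bonds <- attr(crystal, "bond_images")
  adj <- vector("list", n)
  for (b in bonds) {
    adj[[b$i]] <- c(adj[[b$i]], list(list(j = b$j, shift = b$shift)))
    adj[[b$j]] <- c(adj[[b$j]], list(list(j = b$i, shift = -b$shift)))
  }
  uf <- matrix(NA_real_, n, 3)    # unwrapped fractional coords
  for (s in seq_len(n)) {
    if (!is.na(uf[s, 1])) next
    uf[s, ] <- crystal$frac_coords[s, ]
    queue <- s
    while (length(queue) > 0) {
      v <- queue[[1]]; queue <- queue[-1]
      for (e in adj[[v]]) {
        if (is.na(uf[e$j, 1])) {
          # place j at the image bonded to v
          uf[e$j, ] <- uf[v, ] + (crystal$frac_coords[e$j, ] + e$shift -
                                    crystal$frac_coords[v, ])
          queue <- c(queue, e$j)
        }
      }
    }
  }
  ids <- sort(unique(crystal$molecule_of_site))
  mols <- list(); idx <- list(); fracs <- list()
  for (m in ids) {
    w <- which(crystal$molecule_of_site == m)
    pos <- uf[w, , drop = FALSE] %*% cell
    sub <- match(seq_len(n), w)
    bsub <- list()
    for (b in bonds) if (!is.na(sub[b$i]) && !is.na(sub[b$j])) {
      bsub[[length(bsub) + 1]] <- c(sub[b$i], sub[b$j])
    }
    bm <- if (length(bsub)) do.call(rbind, bsub) else matrix(integer(0), ncol = 2)
    mols[[m]] <- molecule(crystal$species[w], pos, bonds = bm)
    idx[[m]] <- w
    fracs[[m]] <- uf[w, , drop = FALSE]
  }
  list(molecules = mols, site_index = idx, frac_unwrapped = fracs)
}

#' Crystal density
#'
#' @param crystal A `csp_crystal`.
#' @return Density in g/cm^3 (total site mass over cell volume).
#' @export
density_gcm3 <- function(crystal) {
  mass_g <- sum(crystal$elements$mass) * csp_constants$u_gram
  vol_cm3 <- cell_volume(crystal$lattice) * 1e-24
  mass_g / vol_cm3
}
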