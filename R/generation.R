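# Random molecular crystal generation: volume estimation from vdW spheres,
# close-contact screening (specific radius ratio s_r on summed vdW radii),
# symmetry-constrained placement on general positions, and a rigid-body
# compression ("rigid press") stage.

#' Contact criterion (specific radius ratio)
#' @param s_r Dimensionless factor scaling summed van der Waals radii into the
#'   minimum allowed intermolecular contact (typically 0.7-0.9).
#' @export
contact_criterion <- function(s_r = 0.8) {
  stopifnot(s_r > 0, s_r <= 1.5)
  list(s_r = s_r)
}

#' Estimate the unit-cell volume from van der Waals spheres
#'
#' `V = Z * sum_atoms (4/3) pi r_vdw^3 / packing_factor`.
#'
#' @param mol A `csp_molecule`.
#' @param Z Molecules per cell.
#' @param packing_factor Packing coefficient (default 0.55, typical for
#'   organic crystals).
#' @param vdw_radii Optional per-atom radius override (Angstrom).
#' @return Estimated volume in A^3.
#' @export
estimate_volume <- function(mol, Z, packing_factor = 0.55, vdw_radii = NULL) {
  r <- if (is.null(vdw_radii)) mol$elements$r_vdw else vdw_radii
  Z * sum(4 / 3 * pi * r^3) / packing_factor
}

#' Intermolecular close contacts violating the s_r criterion
#'
#' Returns every pair of sites belonging to different molecules (periodic
#' images included) whose minimum distance d satisfies
#' `d <= s_r * (r_vdw_A + r_vdw_B)`. Intramolecular pairs are never reported.
#'
#' @param crystal A `csp_crystal`; the molecule partition is computed if
#'   missing.
#' @param criterion A [contact_criterion()].
#' @param bond_scale Bond-detection scale used if the partition is missing.
#' @return data.frame with columns `site_i`, `site_j`, `d`, `threshold`
#'   (one row per violating pair, i <= j).
#' @export
contact_violations <- function(crystal, criterion = contact_criterion(),
                               bond_scale = 1.2) {
  pc <- intermolecular_contacts(crystal, criterion, bond_scale,
                                mode = "violations")
  pc
}

# shared scanner over intermolecular pairs (periodic images included).
# A pair of sites in the same molecule is intramolecular only at the single
# image shift consistent with the unwrapped molecule; all other images are
# contacts of the molecule with its own periodic copies and are screened.
intermolecular_contacts <- function(crystal, criterion, bond_scale = 1.2,
                                    mode = c("violations", "penalty")) {
  mode <- match.arg(mode)
  n <- length(crystal$species)
  ufrac <- attr(crystal, "ufrac")     # unwrapped fracs, when known upstream
  if (is.null(ufrac)) {
    if (is.null(crystal$molecule_of_site) ||
        is.null(attr(crystal, "bond_images"))) {
      crystal <- identify_molecules(crystal, bond_scale)
    }
    uw <- unwrap_molecules(crystal)
    ufrac <- matrix(NA_real_, n, 3)
    for (m in seq_along(uw$site_index)) {
      ufrac[uw$site_index[[m]], ] <- uw$frac_unwrapped[[m]]
    }
  }
  rv <- crystal$elements$r_vdw
  mol <- crystal$molecule_of_site
  cell <- as.matrix(crystal$lattice)
  maxthr <- criterion$s_r * 2 * max(rv)
  nb <- image_bounds(cell, maxthr)
  sh0 <- image_shifts(nb)
  shc <- sh0 %*% cell
  pen <- 0
  out <- list()
  for (i in seq_len(n)) for (j in i:n) {
    thr <- criterion$s_r * (rv[i] + rv[j])
    dfr <- crystal$frac_coords[j, ] - crystal$frac_coords[i, ]
    dc <- shc + matrix(dfr %*% cell, nrow(shc), 3, byrow = TRUE)
    dist <- sqrt(rowSums(dc^2))
    same_mol <- mol[i] == mol[j]
    s_intra <- if (same_mol) {
      round((ufrac[j, ] - ufrac[i, ]) - dfr)
    } else NULL
    for (k in seq_along(dist)) {
      if (same_mol && all(abs(sh0[k, ] - s_intra) < 0.5)) next
      if (mode == "penalty") {
        if (dist[k] < thr) pen <- pen + (thr - dist[k])^2
        next
      }
      if (dist[k] > thr) next
      {
        out[[length(out) + 1]] <- data.frame(site_i = i, site_j = j,
                                             d = dist[k], threshold = thr)
      }
    }
  }
  if (mode == "penalty") return(pen)
  if (length(out) == 0) {
    return(data.frame(site_i = integer(0), site_j = integer(0),
                      d = numeric(0), threshold = numeric(0)))
  }
  do.call(rbind, out)
}

#' Generation configuration
#' @param space_groups Character vector from [supported_space_groups()].
#' @param Z_values Candidate molecules-per-cell counts.
#' @param volume_window Fractional half-width of the volume distribution
#'   around the estimate (default 0.15).
#' @param volume_scale Multiplier on the volume estimate (default 1; values
#'   well below 1 make packing infeasible).
#' @param max_attempts Attempts before giving up (default 200).
#' @param seed Integer seed.
#' @export
generation_config <- function(space_groups = c("P1", "P-1"), Z_values = c(1, 2),
                              volume_window = 0.15, volume_scale = 1,
                              max_attempts = 200, seed = 1L) {
  stopifnot(all(space_groups %in% supported_space_groups()), all(Z_values >= 1))
  list(space_groups = space_groups, Z_values = Z_values,
       volume_window = volume_window, volume_scale = volume_scale,
       max_attempts = max_attempts, seed = as.integer(seed))
}

random_rotation <- function() {
  # uniform rotation via normalized quaternion
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# sample a cell of the given lattice system with the target volume
sample_cell <- function(system, volume) {
  repeat {
    if (system == "triclinic") {
      ang <- stats::runif(3, 60, 120)
    } else if (system == "monoclinic") {
      ang <- c(90, stats::runif(1, 60, 120), 90)
    } else {
      ang <- c(90, 90, 90)
    }
    # random length ratios, then scale to the target volume
    ratios <- exp(stats::runif(3, -0.4, 0.4))
    lat0 <- tryCatch(lattice_from_params(c(ratios, ang)), error = function(e) NULL)
    if (is.null(lat0)) next
    v0 <- cell_volume(lat0)
    s <- (volume / v0)^(1 / 3)
    return(lattice(as.matrix(lat0) * s))
  }
}

#' Generate one random symmetry-constrained crystal candidate
#'
#' Places a molecule at a random position/orientation on a general position,
#' replicates it with the space-group operators, and accepts the candidate
#' when it is free of s_r contact violations; retries up to
#' `config$max_attempts` times.
#'
#' @param mol A rigid `csp_molecule` (the conformer to pack).
#' @param space_group Name from [supported_space_groups()].
#' @param Z Molecules per cell; must be a multiple of the group's
#'   general-position multiplicity.
#' @param criterion A [contact_criterion()].
#' @param config A [generation_config()].
#' @param seed Optional seed overriding `config$seed`.
#' @return A `csp_crystal` with `Z` molecules and zero contact violations, or
#'   an error of class `csp_generation_failure` carrying the attempt count.
#' @export
generate_candidate <- function(mol, space_group, Z, criterion = contact_criterion(),
                               config = generation_config(), seed = NULL) {
  ops <- space_group_ops(space_group)
  mult <- length(ops)
  if (Z %% mult != 0) {
    stop("Z = ", Z, " is not a multiple of the general-position multiplicity ",
         mult, " of ", space_group)
  }
  n_indep <- Z %/% mult
  if (!is.null(seed)) set.seed(seed) else set.seed(config$seed)
  v_est <- estimate_volume(mol, Z) * (config$volume_scale %||% 1)
  nat <- length(mol$symbols)
  for (attempt in seq_len(config$max_attempts)) {
    vol <- v_est * stats::runif(1, 1 - config$volume_window,
                                1 + config$volume_window)
    lat <- sample_cell(sg_system(space_group), vol)
    cell <- as.matrix(lat)
    species <- character(0); fr <- NULL; molid <- integer(0)
    ok <- TRUE
    for (m in seq_len(n_indep)) {
      R <- random_rotation()
      tfrac <- stats::runif(3)
      centred <- sweep(mol$positions, 2, colMeans(mol$positions))
      rot <- centred %*% t(R)
      f0 <- rot %*% solve(cell) + matrix(tfrac, nat, 3, byrow = TRUE)
      for (oi in seq_along(ops)) {
        fo <- t(ops[[oi]]$W %*% t(f0)) +
          matrix(ops[[oi]]$w, nat, 3, byrow = TRUE)
        species <- c(species, mol$symbols)
        fr <- rbind(fr, fo)
        molid <- c(molid, rep((m - 1) * mult + oi, nat))
      }
    }
    cand <- crystal_structure(lat, species, fr, Z = Z,
                              space_group = sg_number(space_group),
                              molecule_of_site = molid)
    attr(cand, "ufrac") <- fr
    viol <- contact_violations(cand, criterion)
    if (nrow(viol) == 0) {
      attr(cand, "attempts") <- attempt
      return(cand)
    }
  }
  cond <- structure(class = c("csp_generation_failure", "error", "condition"),
                    list(message = paste0("generation failed after ",
                                          config$max_attempts, " attempts"),
                         call = sys.call(), attempts = config$max_attempts))
  stop(cond)
}

# rigid-body parameterization: per molecule translation (frac) + rotation
# vector; cell via symmetric strain on the starting cell.
rigid_assemble <- function(cell0, strain, mols_local, centers0, theta) {
  eps <- matrix(0, 3, 3)
  eps[upper.tri(eps, diag = TRUE)] <- strain
  eps <- (eps + t(eps)) / 2
  cell <- cell0 %*% (diag(3) + eps)
  species <- character(0); fr <- NULL; molid <- integer(0)
  for (m in seq_along(mols_local)) {
    R <- rotvec_matrix(theta[[m]]$rot)
    pos <- mols_local[[m]]$positions %*% t(R)
    ctr <- (centers0[m, ] + theta[[m]]$trans)
    f <- pos %*% solve(cell) + matrix(ctr, nrow(pos), 3, byrow = TRUE)
    species <- c(species, mols_local[[m]]$symbols)
    fr <- rbind(fr, f)
    molid <- c(molid, rep(m, nrow(pos)))
  }
  cs <- crystal_structure(lattice(cell), species, fr, Z = length(mols_local),
                          molecule_of_site = molid)
  attr(cs, "ufrac") <- fr
  cs
}

rotvec_matrix <- function(v) {
  th <- sqrt(sum(v^2))
  if (th < 1e-12) return(diag(3))
  k <- v / th
  K <- matrix(c(0, -k[3], k[2], k[3], 0, -k[1], -k[2], k[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
}

# smooth overlap penalty sum(max(0, thr - d)^2) over intermolecular contacts
overlap_penalty <- function(crystal, criterion) {
  intermolecular_contacts(crystal, criterion, mode = "penalty")
}

#' Compress a molecular crystal with rigid bodies ("rigid press")
#'
#' The cell is first expanded isotropically by `expansion_factor`, then
#' compressed by gradient descent with backtracking on a smooth overlap
#' penalty plus a shrinking volume objective, treating each molecule as a
#' rigid body (translations + rotations; internal geometry preserved).
#' Space-group symmetry is not preserved. Stops when the overlap penalty is
#' zero and the volume step falls below 0.1%.
#'
#' @param crystal A `csp_crystal` with a molecule partition.
#' @param criterion A [contact_criterion()].
#' @param expansion_factor Initial isotropic expansion (default 1.6).
#' @param max_iter Iteration budget for the shrink loop (default 400).
#' @return The compressed `csp_crystal`; attribute `"converged"` is FALSE
#'   when the budget ran out (best-so-far returned with a warning).
#' @export
rigid_press <- function(crystal, criterion = contact_criterion(),
                        expansion_factor = 1.6, max_iter = 400) {
  uw <- unwrap_molecules(crystal)
  mols_local <- lapply(uw$molecules, function(m) {
    m$positions <- sweep(m$positions, 2, colMeans(m$positions))
    m
  })
  cell_init <- as.matrix(crystal$lattice) * expansion_factor
  centers0 <- do.call(rbind, lapply(uw$frac_unwrapped, colMeans))
  nm <- length(mols_local)
  nat <- vapply(mols_local, function(m) length(m$symbols), 0L)
  molid <- rep(seq_len(nm), nat)
  rv <- unlist(lapply(mols_local, function(m) m$elements$r_vdw))
  sr <- criterion$s_r
  maxthr <- sr * 2 * max(rv)

  assemble <- function(v) {
    eps <- matrix(0, 3, 3)
    eps[upper.tri(eps, diag = TRUE)] <- v[1:6]
    eps <- (eps + t(eps)) / 2
    cell <- cell_init %*% (diag(3) + eps)
    fr <- NULL
    for (m in seq_len(nm)) {
      off <- 6 + (m - 1) * 6
      R <- rotvec_matrix(v[off + 4:6])
      pos <- mols_local[[m]]$positions %*% t(R)
      ctr <- centers0[m, ] + v[off + 1:3]
      fr <- rbind(fr, pos %*% solve(cell) +
                    matrix(ctr, nrow(pos), 3, byrow = TRUE))
    }
    list(cell = cell, fr = fr)
  }
  pen_of <- function(cell, fr) {
    n <- nrow(fr)
    nb <- image_bounds(cell, maxthr)
    sh0 <- image_shifts(nb)
    shc <- sh0 %*% cell
    pen <- 0
    for (i in seq_len(n)) for (j in i:n) {
      thr <- sr * (rv[i] + rv[j])
      dfr <- fr[j, ] - fr[i, ]
      base <- round(dfr)
      d0 <- dfr - base
      dc <- shc + matrix(d0 %*% cell, nrow(shc), 3, byrow = TRUE)
      dd <- sqrt(rowSums(dc^2))
      if (molid[i] == molid[j]) {
        # the intramolecular image (shift == base in wrapped frame) is exempt
        excl <- which(sh0[, 1] == base[1] & sh0[, 2] == base[2] &
                        sh0[, 3] == base[3])
        if (length(excl)) dd <- dd[-excl]
      }
      o <- dd[dd < thr]
      if (length(o)) pen <- pen + sum((thr - o)^2)
    }
    pen
  }
  pen_f <- function(v) { a <- assemble(v); pen_of(a$cell, a$fr) }
  vol_f <- function(v) abs(det(assemble(v)$cell))

  v <- rep(0, 6 + 6 * nm)
  min_pen <- function(v) {
    # descend the penalty to (near) zero; the isotropic strain component is
    # projected out so overlaps are relieved by shape and rigid-body moves,
    # not by undoing the compression
    for (it in 1:50) {
      p0 <- pen_f(v)
      if (p0 <= 1e-14) return(list(v = v, pen = p0))
      g <- num_grad(pen_f, v)
      tr <- (g[1] + g[3] + g[6]) / 3
      g[c(1, 3, 6)] <- g[c(1, 3, 6)] - tr
      gn <- sqrt(sum(g^2))
      if (gn < 1e-14) return(list(v = v, pen = p0))
      step <- 0.1 / gn
      repeat {
        vt <- v - step * g
        if (pen_f(vt) < p0) { v <- vt; break }
        step <- step / 2
        if (step * gn < 1e-10) return(list(v = v, pen = p0))
      }
    }
    list(v = v, pen = pen_f(v))
  }
  res <- min_pen(v)
  v <- res$v
  shrink <- 0.04
  iters <- 0
  idx_diag <- c(1, 3, 6)   # diagonal of the upper-tri strain packing
  while (shrink >= 0.001 && iters < max_iter) {
    iters <- iters + 1
    vtry <- v
    vtry[idx_diag] <- vtry[idx_diag] - shrink
    res <- min_pen(vtry)
    if (res$pen <= 1e-14 && vol_f(res$v) < vol_f(v)) {
      v <- res$v
    } else {
      shrink <- shrink / 2
    }
  }
  res <- min_pen(v)
  u <- unpack_press(res$v, nm)
  out <- rigid_assemble(cell_init, u$strain, mols_local, centers0, u$theta)
  conv <- res$pen <= 1e-14
  if (!conv) warning("rigid press did not fully remove overlaps")
  out$space_group <- NA_integer_
  attr(out, "converged") <- conv
  out
}

unpack_press <- function(v, nm) {
  th <- list()
  for (m in seq_len(nm)) {
    off <- 6 + (m - 1) * 6
    th[[m]] <- list(trans = v[off + 1:3], rot = v[off + 4:6])
  }
  list(strain = v[1:6], theta = th)
}

num_grad <- function(f, v, h = 1e-5) {
  g <- numeric(length(v))
  for (i in seq_along(v)) {
    vp <- v; vp[i] <- vp[i] + h
    vm <- v; vm[i] <- vm[i] - h
    g[i] <- (f(vp) - f(vm)) / (2 * h)
  }
  g
}
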