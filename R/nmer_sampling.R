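# Molecular shells and n-mer extraction from crystals, plus tethered
# finite-temperature Langevin sampling to diversify cluster geometries.

#' Extract the molecular shell around a central molecule
#'
#' A molecule (or any of its periodic images) belongs to the shell iff any of
#' its atoms lies within `cutoff` of any atom of the central molecule. All
#' members are returned whole and unwrapped (no bond crosses an image
#' boundary), in Cartesian coordinates, central molecule first. Distinct
#' periodic images of the same molecule count as distinct members.
#'
#' @param crystal A `csp_crystal`.
#' @param center_molecule Molecule id (1-based, from [identify_molecules()]).
#' @param cutoff Shell cutoff in Angstrom.
#' @param bond_scale Bond-detection scale if the partition is missing.
#' @return List of `csp_molecule`; attribute `"members"` records
#'   (molecule id, image shift) per entry.
#' @export
molecular_shell <- function(crystal, center_molecule, cutoff, bond_scale = 1.2) {
  stopifnot(cutoff > 0)
  if (is.null(crystal$molecule_of_site) ||
      is.null(attr(crystal, "bond_images"))) {
    crystal <- identify_molecules(crystal, bond_scale)
  }
  uw <- unwrap_molecules(crystal)
  nmol <- length(uw$molecules)
  if (center_molecule < 1 || center_molecule > nmol) {
    stop("invalid center molecule id ", center_molecule)
  }
  cell <- as.matrix(crystal$lattice)
  cen_pos <- uw$frac_unwrapped[[center_molecule]] %*% cell
  # image range: cutoff plus the largest molecular extent
  ext <- max(vapply(uw$frac_unwrapped, function(f) {
    p <- f %*% cell
    max(stats::dist(rbind(p, p[1, , drop = FALSE])))
  }, 0))
  nb <- image_bounds(cell, cutoff + ext + 1e-9)
  sh <- image_shifts(nb)
  members <- list(list(id = center_molecule, shift = c(0, 0, 0)))
  mols <- list(shift_molecule(uw$molecules[[center_molecule]], c(0, 0, 0), cell,
                              uw$frac_unwrapped[[center_molecule]]))
  for (m in seq_len(nmol)) {
    for (k in seq_len(nrow(sh))) {
      s <- as.numeric(sh[k, ])
      if (m == center_molecule && all(s == 0)) next
      pos <- (uw$frac_unwrapped[[m]] +
                matrix(s, nrow(uw$frac_unwrapped[[m]]), 3, byrow = TRUE)) %*% cell
      dmin <- min_cross_dist(pos, cen_pos)
      if (dmin <= cutoff) {
        members[[length(members) + 1]] <- list(id = m, shift = s)
        mols[[length(mols) + 1]] <-
          shift_molecule(uw$molecules[[m]], s, cell, uw$frac_unwrapped[[m]])
      }
    }
  }
  attr(mols, "members") <- members
  mols
}

min_cross_dist <- function(A, B) {
  # minimum pairwise distance between two point sets
  best <- Inf
  for (i in seq_len(nrow(A))) {
    d2 <- rowSums((B - matrix(A[i, ], nrow(B), 3, byrow = TRUE))^2)
    best <- min(best, min(d2))
  }
  sqrt(best)
}

shift_molecule <- function(mol, shift, cell, frac_unwrapped) {
  pos <- (frac_unwrapped + matrix(shift, nrow(frac_unwrapped), 3,
                                  byrow = TRUE)) %*% cell
  molecule(mol$symbols, pos, bonds = mol$bonds,
           formal_charge = mol$formal_charge)
}

#' Enumerate n-mers from a crystal
#'
#' For each order n up to `n_max`, builds n-mers consisting of the central
#' molecule plus (n-1) shell members. Members are ranked by ascending minimum
#' intermolecular atom-atom distance to the central molecule; the first n-mer
#' of each order takes the (n-1) nearest members, further ones are random
#' combinations (seeded, no duplicates) up to `per_order_counts`.
#'
#' @param crystal A `csp_crystal`.
#' @param n_max Highest order (1-8).
#' @param per_order_counts Number of n-mers per order (recycled to length
#'   `n_max`).
#' @param seed Integer seed.
#' @param center_molecule Central molecule id (default 1).
#' @param cutoff Shell cutoff (default 8 A).
#' @return List of `csp_nmer`; attribute `"flagged"` names orders whose shell
#'   was too small for the requested count.
#' @export
enumerate_nmers <- function(crystal, n_max, per_order_counts = 1, seed = 1L,
                            center_molecule = 1, cutoff = 8) {
  stopifnot(n_max >= 1, n_max <= 8)
  counts <- rep(per_order_counts, length.out = n_max)
  shell <- molecular_shell(crystal, center_molecule, cutoff)
  central <- shell[[1]]
  others <- shell[-1]
  # rank shell members by minimum distance to the central molecule
  if (length(others) > 0) {
    dmin <- vapply(others, function(m) {
      min_cross_dist(m$positions, central$positions)
    }, 0)
    others <- others[order(dmin)]
  }
  out <- list()
  flagged <- integer(0)
  set.seed(seed)
  for (n in seq_len(n_max)) {
    if (n == 1) {
      if (counts[1] >= 1) out[[length(out) + 1]] <- nmer(list(central))
      next
    }
    avail <- length(others)
    if (avail < n - 1) { flagged <- c(flagged, n); next }
    combos <- list()
    # nearest-neighbour combination first
    combos[[1]] <- seq_len(n - 1)
    n_comb_total <- choose(avail, n - 1)
    tries <- 0
    while (length(combos) < min(counts[n], n_comb_total) && tries < 1000) {
      tries <- tries + 1
      cand <- sort(sample(avail, n - 1))
      if (!any(vapply(combos, function(cb) identical(cb, cand), TRUE))) {
        combos[[length(combos) + 1]] <- cand
      }
    }
    if (counts[n] > n_comb_total) flagged <- c(flagged, n)
    for (cb in combos) {
      out[[length(out) + 1]] <- nmer(c(list(central), others[cb]))
    }
  }
  attr(out, "flagged") <- flagged
  out
}

#' Tether settings for constrained Langevin sampling
#' @param k_tether Harmonic tether constant, eV/A^2 (default 0.005).
#' @param temperature Kelvin (default 300).
#' @param n_steps MD steps (default 5000).
#' @param timestep fs (default 1).
#' @param friction Langevin friction, 1/fs (default 0.01).
#' @param stride Frame subsampling stride (default 100).
#' @param seed Integer seed.
#' @export
tether_settings <- function(k_tether = 0.005, temperature = 300,
                            n_steps = 5000, timestep = 1, friction = 0.01,
                            stride = 100, seed = 1L) {
  stopifnot(k_tether >= 0, temperature >= 0)
  list(k_tether = k_tether, temperature = temperature, n_steps = n_steps,
       timestep = timestep, friction = friction, stride = stride,
       seed = as.integer(seed))
}

#' Tethered Langevin sampling of a cluster
#'
#' BAOAB Langevin dynamics at `settings$temperature` with a per-atom harmonic
#' tether `k_tether |x - x0|^2` to the starting geometry and no bond
#' constraints. Deterministic per seed; frames are subsampled at the stride.
#'
#' @param geom A `csp_nmer` or `csp_molecule` (starting geometry = tether
#'   reference).
#' @param calculator Forces provider.
#' @param settings A [tether_settings()].
#' @return List of perturbed geometries (same class as the input).
#' @export
tethered_sampling <- function(geom, calculator, settings = tether_settings()) {
  at <- as_atoms(geom)
  x0 <- at$positions
  n <- nrow(x0)
  masses <- element_spec(at$symbols)$mass
  # unit bookkeeping: x in A, t in fs, m in amu, E in eV;
  # 1 eV/(A amu) = 9.6485e-3 A/fs^2
  acc_unit <- csp_constants$eV_J / csp_constants$amu_kg * 1e-10
  kB <- csp_constants$k_B
  dt <- settings$timestep
  gam <- settings$friction
  set.seed(settings$seed)
  x <- x0
  v <- matrix(0, n, 3)       # A/fs
  if (settings$temperature > 0) {
    sd_v <- sqrt(kB * settings$temperature / masses * acc_unit)
    v <- matrix(stats::rnorm(3 * n), n, 3) * sd_v
  }
  forces_at <- function(x) {
    f <- calc_eval(calculator, geom_set_positions(geom, x), forces = TRUE)$forces
    if (any(!is.finite(f))) stop("non-finite forces during tethered sampling")
    f - 2 * settings$k_tether * (x - x0)
  }
  f <- forces_at(x)
  c1 <- exp(-gam * dt)
  c2 <- if (settings$temperature > 0) {
    sqrt((1 - c1^2) * kB * settings$temperature * acc_unit)
  } else 0
  frames <- list()
  for (step in seq_len(settings$n_steps)) {
    v <- v + 0.5 * dt * f / masses * acc_unit
    x <- x + 0.5 * dt * v
    if (settings$temperature >= 0) {
      v <- c1 * v + c2 / sqrt(masses) * matrix(stats::rnorm(3 * n), n, 3)
    }
    x <- x + 0.5 * dt * v
    f <- forces_at(x)
    v <- v + 0.5 * dt * f / masses * acc_unit
    if (step %% settings$stride == 0) {
      frames[[length(frames) + 1]] <- geom_set_positions(geom, x)
    }
  }
  frames
}
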