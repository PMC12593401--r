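# shared test fixtures and independent oracles

ar_lj <- function(eps = 0.0104, sigma = 3.4, cutoff = 8, shift = TRUE) {
  pair_potential("lj", list("Ar-Ar" = c(eps = eps, sigma = sigma)),
                 cutoff = cutoff, shift = shift)
}

# flexible-diatomic molecular teacher: intermolecular LJ + harmonic bonds
n2_teacher <- function(eps = 0.02, sigma = 3.0, k_bond = 30, r0 = 1.10) {
  composite_calculator(
    pair_potential("lj", list("N-N" = c(eps = eps, sigma = sigma)),
                   cutoff = 9, intermolecular_only = TRUE),
    bond_calculator(k = k_bond, r0 = r0))
}

# random skewed (but not degenerate) lattice
random_lattice <- function() {
  repeat {
    cell <- matrix(stats::rnorm(9, sd = 3), 3, 3) + diag(3) * 8
    if (det(cell) > 50) return(lattice(cell))
  }
}

# independent minimum-image oracle: explicit 5x5x5 image enumeration
brute_min_image <- function(cell, f1, f2) {
  cell <- as.matrix(cell)
  best <- Inf
  for (i in -2:2) for (j in -2:2) for (k in -2:2) {
    d <- (f2 + c(i, j, k) - f1) %*% cell
    best <- min(best, sqrt(sum(d^2)))
  }
  best
}

# independent contact oracle: all intermolecular (incl. self-image) pairs
# with d <= s_r (r_i + r_j) by explicit image enumeration
brute_contacts <- function(crystal, s_r, images = 2) {
  cell <- as.matrix(crystal$lattice)
  rv <- crystal$elements$r_vdw
  mol <- crystal$molecule_of_site
  n <- length(crystal$species)
  cnt <- 0
  for (i in seq_len(n)) for (j in i:n) {
    thr <- s_r * (rv[i] + rv[j])
    for (ii in -images:images) for (jj in -images:images) for (kk in -images:images) {
      sh <- c(ii, jj, kk)
      if (i == j && all(sh == 0)) next
      same_copy <- !is.null(mol) && mol[i] == mol[j] && all(sh == 0)
      if (same_copy) next
      d <- sqrt(sum(((crystal$frac_coords[j, ] + sh -
                        crystal$frac_coords[i, ]) %*% cell)^2))
      if (d <= thr) cnt <- cnt + 1
    }
  }
  cnt
}

expect_close <- function(x, y, tol = 1e-8) {
  expect_true(max(abs(x - y)) <= tol,
              label = sprintf("max|%.3g - %.3g| = %.3g <= %g",
                              x[1], y[1], max(abs(x - y)), tol))
}
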