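# Calculator contract: every energy model implements calc_eval(calc, geom,
# forces=, stress=) returning list(energy, forces, stress) in eV, eV/Angstrom
# and eV/Angstrom^3. Stress is dE/d(strain)/V (positive trace under
# compression of an attractive system); forces are -dE/dx. Models lacking an
# analytic derivative fall back to central differences.

#' Evaluate a calculator on a geometry
#'
#' @param calc A calculator object (see [pair_potential()], [ewald_calculator()],
#'   [einstein_calculator()], [surrogate_calculator()], [composite_calculator()]).
#' @param geom A `csp_crystal`, `csp_molecule` or `csp_nmer`.
#' @param forces,stress Request forces / stress (stress requires a periodic
#'   geometry).
#' @return List with `energy` (eV), `forces` (Nx3, eV/A) and `stress`
#'   (3x3, eV/A^3) as requested.
#' @export
calc_eval <- function(calc, geom, forces = FALSE, stress = FALSE) {
  UseMethod("calc_eval")
}

#' @rdname calc_eval
#' @export
calc_capabilities <- function(calc) {
  caps <- attr(calc, "capabilities")
  if (is.null(caps)) caps <- c(energy = TRUE, forces = FALSE, stress = FALSE,
                               analytic_hessian = FALSE, charges = FALSE)
  caps
}

geom_positions <- function(geom) as_atoms(geom)$positions

geom_set_positions <- function(geom, pos) {
  if (inherits(geom, "csp_crystal")) {
    geom$frac_coords <- coords_convert(geom$lattice, pos, "cart_to_frac") %% 1
  } else if (inherits(geom, "csp_molecule")) {
    geom$positions <- pos
  } else if (inherits(geom, "csp_nmer")) {
    k <- 0
    for (m in seq_along(geom$molecules)) {
      nm <- nrow(geom$molecules[[m]]$positions)
      geom$molecules[[m]]$positions <- pos[(k + 1):(k + nm), , drop = FALSE]
      k <- k + nm
    }
  } else stop("unsupported geometry")
  geom
}

# central-difference forces, h in Angstrom
numerical_forces <- function(calc, geom, h = 1e-4) {
  pos <- geom_positions(geom)
  f <- pos * 0
  for (i in seq_len(nrow(pos))) for (a in 1:3) {
    pp <- pos; pp[i, a] <- pp[i, a] + h
    ep <- calc_eval(calc, geom_set_positions(geom, pp))$energy
    pp[i, a] <- pos[i, a] - h
    em <- calc_eval(calc, geom_set_positions(geom, pp))$energy
    f[i, a] <- -(ep - em) / (2 * h)
  }
  f
}

# central-difference stress via symmetric strain, periodic geometries only
numerical_stress <- function(calc, geom, h = 1e-5) {
  stopifnot(inherits(geom, "csp_crystal"))
  cell0 <- as.matrix(geom$lattice)
  V <- cell_volume(cell0)
  s <- matrix(0, 3, 3)
  strain_energy <- function(eps) {
    g <- geom
    g$lattice <- lattice(cell0 %*% (diag(3) + eps))
    calc_eval(calc, g)$energy
  }
  for (a in 1:3) for (b in a:3) {
    eps <- matrix(0, 3, 3)
    eps[a, b] <- eps[a, b] + h / 2; eps[b, a] <- eps[b, a] + h / 2
    ep <- strain_energy(eps)
    em <- strain_energy(-eps)
    s[a, b] <- s[b, a] <- (ep - em) / (2 * h) / V
  }
  s
}

# ---------------------------------------------------------------------------
# pair potentials (Lennard-Jones, Buckingham, harmonic springs)

pair_key <- function(s1, s2) paste(sort(c(s1, s2)), collapse = "-")

#' Pair-potential calculator
#'
#' Supported forms, per species pair:
#' \itemize{
#'   \item `"lj"`: `4 eps ((sigma/r)^12 - (sigma/r)^6)`, parameters
#'     `eps` (eV) and `sigma` (A);
#'   \item `"buckingham"`: `A exp(-r/rho) - C/r^6`, parameters `A` (eV),
#'     `rho` (A), `C` (eV A^6);
#'   \item `"harmonic"`: `k/2 (r - r0)^2`, parameters `k` (eV/A^2), `r0` (A)
#'     (a bonded-spring stand-in, cutoff-limited).
#' }
#' Periodic sums run over all lattice images within the cutoff (which makes
#' supercell energies exactly extensive). Forces, stress and the analytic
#' Hessian are available.
#'
#' @param type One of `"lj"`, `"buckingham"`, `"harmonic"`.
#' @param params Named list: `params[["A-B"]]` is a named numeric vector of
#'   parameters for the (sorted) species pair.
#' @param cutoff Interaction cutoff in Angstrom.
#' @param shift Shift the potential to zero at the cutoff (default TRUE for
#'   `"lj"`/`"buckingham"`).
#' @param intermolecular_only Restrict the sum to pairs from different
#'   molecules (default FALSE); combine with [bond_calculator()] for
#'   flexible-molecule teachers.
#' @return A calculator object.
#' @examples
#' lj <- pair_potential("lj", list("Ar-Ar" = c(eps = 0.0104, sigma = 3.4)),
#'                      cutoff = 8.5)
#' @export
pair_potential <- function(type = c("lj", "buckingham", "harmonic"), params,
                           cutoff, shift = type != "harmonic",
                           intermolecular_only = FALSE) {
  type <- match.arg(type)
  stopifnot(cutoff > 0)
  structure(list(type = type, params = params, cutoff = cutoff, shift = shift,
                 intermolecular_only = intermolecular_only),
            class = c("csp_calc_pair", "csp_calculator"),
            capabilities = c(energy = TRUE, forces = TRUE, stress = TRUE,
                             analytic_hessian = TRUE, charges = FALSE))
}

# phi, phi', phi'' for a pair type; vectorised over r
pair_phi <- function(calc, key, r, deriv = 0) {
  p <- calc$params[[key]]
  if (is.null(p)) stop("missing pair parameters for ", key)
  sh <- 0
  if (calc$shift && deriv == 0) sh <- pair_phi_raw(calc$type, p, calc$cutoff, 0)
  pair_phi_raw(calc$type, p, r, deriv) - sh
}

pair_phi_raw <- function(type, p, r, deriv) {
  if (type == "lj") {
    sr6 <- (p[["sigma"]] / r)^6
    if (deriv == 0) return(4 * p[["eps"]] * (sr6^2 - sr6))
    if (deriv == 1) return(4 * p[["eps"]] * (-12 * sr6^2 + 6 * sr6) / r)
    return(4 * p[["eps"]] * (156 * sr6^2 - 42 * sr6) / r^2)
  }
  if (type == "buckingham") {
    ex <- p[["A"]] * exp(-r / p[["rho"]])
    if (deriv == 0) return(ex - p[["C"]] / r^6)
    if (deriv == 1) return(-ex / p[["rho"]] + 6 * p[["C"]] / r^7)
    return(ex / p[["rho"]]^2 - 42 * p[["C"]] / r^8)
  }
  # harmonic
  if (deriv == 0) return(0.5 * p[["k"]] * (r - p[["r0"]])^2)
  if (deriv == 1) return(p[["k"]] * (r - p[["r0"]]))
  rep(p[["k"]], length(r))
}

# enumerate ordered interacting pairs: data.frame(i, j, rvec, r) with each
# unordered interaction appearing twice (i->j and j->i); periodic images
# included for crystals. Used by energy/forces/stress/hessian alike.
pair_list <- function(geom, cutoff, intermolecular_only = FALSE) {
  at <- as_atoms(geom)
  pos <- at$positions
  n <- nrow(pos)
  mol <- at$mol_id
  skip_same <- intermolecular_only && !is.null(mol)
  ii <- integer(0); jj <- integer(0); rv <- NULL
  if (inherits(geom, "csp_crystal")) {
    cell <- as.matrix(geom$lattice)
    nb <- image_bounds(cell, cutoff)
    sh <- image_shifts(nb) %*% cell
    sh_raw <- NULL
    if (skip_same) {
      # intramolecular image per same-molecule pair, from unwrapped coords
      ufrac <- attr(geom, "ufrac")
      if (is.null(ufrac)) {
        uw <- unwrap_molecules(geom)
        ufrac <- matrix(NA_real_, n, 3)
        for (m in seq_along(uw$site_index)) {
          ufrac[uw$site_index[[m]], ] <- uw$frac_unwrapped[[m]]
        }
        mol <- geom$molecule_of_site %||% mol
      }
    }
    nb <- image_bounds(cell, cutoff)
    sh_int <- image_shifts(nb)
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        d0 <- pos[j, ] - pos[i, ]
        dc <- sh + matrix(d0, nrow(sh), 3, byrow = TRUE)
        r2 <- rowSums(dc^2)
        keep <- which(r2 <= cutoff^2 & r2 > 1e-12)
        if (skip_same && length(keep) && !is.null(mol) && mol[i] == mol[j]) {
          dfr <- geom$frac_coords[j, ] - geom$frac_coords[i, ]
          s_intra <- round((ufrac[j, ] - ufrac[i, ]) - dfr)
          bad <- vapply(keep, function(k) all(abs(sh_int[k, ] - s_intra) < 0.5),
                        TRUE)
          keep <- keep[!bad]
        }
        if (length(keep)) {
          ii <- c(ii, rep(i, length(keep))); jj <- c(jj, rep(j, length(keep)))
          rv <- rbind(rv, dc[keep, , drop = FALSE])
        }
      }
    }
  } else {
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j) next
      if (skip_same && mol[i] == mol[j]) next
      d <- pos[j, ] - pos[i, ]
      if (sum(d^2) <= cutoff^2) {
        ii <- c(ii, i); jj <- c(jj, j); rv <- rbind(rv, d)
      }
    }
  }
  list(i = ii, j = jj, rvec = rv,
       r = if (is.null(rv)) numeric(0) else sqrt(rowSums(rv^2)),
       symbols = at$symbols, n = n)
}

#' @rdname calc_eval
#' @export
calc_eval.csp_calc_pair <- function(calc, geom, forces = FALSE, stress = FALSE) {
  pl <- pair_list(geom, calc$cutoff, isTRUE(calc$intermolecular_only))
  n <- pl$n
  E <- 0
  F <- matrix(0, n, 3)
  S <- matrix(0, 3, 3)
  if (length(pl$r) > 0) {
    keys <- pair_key_vec(pl$symbols[pl$i], pl$symbols[pl$j])
    for (key in unique(keys)) {
      w <- which(keys == key)
      r <- pl$r[w]
      E <- E + 0.5 * sum(pair_phi(calc, key, r, 0))
      if (forces || stress) {
        dphi <- pair_phi(calc, key, r, 1)
        u <- pl$rvec[w, , drop = FALSE] / r
        if (forces) {
          contrib <- u * dphi          # force on i along +rvec when dphi>0
          for (a in 1:3) F[, a] <- F[, a] +
              as.numeric(tapply(contrib[, a], factor(pl$i[w], levels = 1:n), sum,
                                default = 0))
        }
        if (stress) {
          rv <- pl$rvec[w, , drop = FALSE]
          for (a in 1:3) for (b in 1:3) {
            S[a, b] <- S[a, b] + 0.5 * sum(dphi / r * rv[, a] * rv[, b])
          }
        }
      }
    }
  }
  out <- list(energy = E)
  if (forces) out$forces <- F
  if (stress) {
    V <- cell_volume(geom$lattice)
    out$stress <- S / V
  }
  out
}

pair_key_vec <- function(s1, s2) {
  a <- pmin(s1, s2); b <- pmax(s1, s2)
  paste(a, b, sep = "-")
}

#' Analytic Hessian of a calculator
#'
#' Second derivatives of the total energy with respect to Cartesian site
#' displacements (3N x 3N, eV/A^2), with periodic image sums for crystals.
#' Implemented for pair potentials and the Einstein calculator.
#'
#' @param calc A calculator with the `analytic_hessian` capability.
#' @param geom Geometry.
#' @return 3N x 3N symmetric matrix.
#' @export
calc_hessian <- function(calc, geom) UseMethod("calc_hessian")

#' @rdname calc_hessian
#' @export
calc_hessian.csp_calc_einstein <- function(calc, geom) {
  n <- nrow(geom_positions(geom))
  diag(calc$k, 3 * n)
}

#' @rdname calc_hessian
#' @export
calc_hessian.csp_calc_pair <- function(calc, geom) pair_hessian(calc, geom)

#' @rdname calc_hessian
#' @param ... ignored.
#' @export
pair_hessian <- function(calc, geom) {
  pl <- pair_list(geom, calc$cutoff, isTRUE(calc$intermolecular_only))
  n <- pl$n
  H <- matrix(0, 3 * n, 3 * n)
  if (length(pl$r) == 0) return(H)
  keys <- pair_key_vec(pl$symbols[pl$i], pl$symbols[pl$j])
  for (k in seq_along(pl$r)) {
    r <- pl$r[k]
    u <- pl$rvec[k, ] / r
    d1 <- pair_phi(calc, keys[k], r, 1)
    d2 <- pair_phi(calc, keys[k], r, 2)
    K <- (d2 - d1 / r) * outer(u, u) + (d1 / r) * diag(3)
    i <- pl$i[k]; j <- pl$j[k]
    bi <- (3 * i - 2):(3 * i); bj <- (3 * j - 2):(3 * j)
    H[bi, bi] <- H[bi, bi] + 0.5 * K
    H[bj, bj] <- H[bj, bj] + 0.5 * K
    H[bi, bj] <- H[bi, bj] - 0.5 * K
    H[bj, bi] <- H[bj, bi] - 0.5 * K
  }
  (H + t(H)) / 2
}

# ---------------------------------------------------------------------------
# Einstein crystal: independent site springs (no coupling)

#' Einstein-crystal calculator
#'
#' `E = k/2 sum_i |x_i - x0_i|^2` about stored reference positions; every
#' vibrational mode has frequency `sqrt(k/m)`.
#'
#' @param reference A `csp_crystal` providing the tether sites.
#' @param k Spring constant, eV/A^2.
#' @export
einstein_calculator <- function(reference, k) {
  x0 <- coords_convert(reference$lattice, reference$frac_coords, "frac_to_cart")
  structure(list(x0 = x0, k = k),
            class = c("csp_calc_einstein", "csp_calculator"),
            capabilities = c(energy = TRUE, forces = TRUE, stress = FALSE,
                             analytic_hessian = TRUE, charges = FALSE))
}

#' @rdname calc_eval
#' @export
calc_eval.csp_calc_einstein <- function(calc, geom, forces = FALSE, stress = FALSE) {
  pos <- geom_positions(geom)
  # displacement by nearest image in the reference cell
  d <- pos - calc$x0
  if (inherits(geom, "csp_crystal")) {
    df <- coords_convert(geom$lattice, d, "cart_to_frac")
    d <- min_image_cart(as.matrix(geom$lattice), df)
  }
  out <- list(energy = 0.5 * calc$k * sum(d^2))
  if (forces) out$forces <- -calc$k * d
  if (stress) out$stress <- matrix(0, 3, 3)
  out
}

# ---------------------------------------------------------------------------
# Ewald summation for point charges

#' Ewald settings
#' @param accuracy Relative accuracy target (default 1e-8).
#' @param real_cutoff Real-space cutoff in Angstrom (default 15).
#' @param alpha Optional splitting parameter (1/A); when supplied, the real
#'   and reciprocal cutoffs are derived from `accuracy` so the result stays
#'   independent of `alpha` to within ~10x the accuracy.
#' @export
ewald_settings <- function(accuracy = 1e-8, real_cutoff = 15, alpha = NULL) {
  stopifnot(accuracy > 0, accuracy <= 1e-2, real_cutoff > 0)
  list(accuracy = accuracy, real_cutoff = real_cutoff, alpha = alpha)
}

#' Ewald energy of a periodic point-charge system
#'
#' @param crystal A `csp_crystal` whose `charges` sum to zero.
#' @param charges Optional per-site charge override (e).
#' @param settings An [ewald_settings()] list.
#' @param forces Also return analytic forces.
#' @return List with `energy` (eV) and optionally `forces`.
#' @export
ewald_energy <- function(crystal, charges = NULL, settings = ewald_settings(),
                         forces = FALSE) {
  q <- if (is.null(charges)) crystal$charges else as.numeric(charges)
  n <- length(crystal$species)
  stopifnot(length(q) == n)
  if (abs(sum(q)) > 1e-10) {
    stop("Ewald requires a neutral cell; net charge = ", sum(q))
  }
  ke <- csp_constants$coulomb
  out0 <- list(energy = 0)
  if (forces) out0$forces <- matrix(0, n, 3)
  if (all(q == 0)) return(out0)
  cell <- as.matrix(crystal$lattice)
  V <- cell_volume(cell)
  pos <- crystal$frac_coords %*% cell
  lg <- sqrt(-log(settings$accuracy))
  if (is.null(settings$alpha)) {
    alpha <- lg / settings$real_cutoff
    rc <- settings$real_cutoff
  } else {
    alpha <- settings$alpha
    rc <- lg / alpha
  }
  kmax <- 2 * alpha * lg

  E <- 0
  F <- matrix(0, n, 3)
  # real-space
  nb <- image_bounds(cell, rc)
  sh <- image_shifts(nb) %*% cell
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      d0 <- pos[i, ] - pos[j, ]
      dc <- sh + matrix(d0, nrow(sh), 3, byrow = TRUE)
      r2 <- rowSums(dc^2)
      keep <- which(r2 <= rc^2 & r2 > 1e-12)
      if (!length(keep)) next
      r <- sqrt(r2[keep])
      E <- E + 0.5 * ke * q[i] * q[j] * sum(erfc_(alpha * r) / r)
      if (forces) {
        coef <- ke * q[i] * q[j] *
          (erfc_(alpha * r) / r^2 + 2 * alpha / sqrt(pi) * exp(-(alpha * r)^2) / r)
        F[i, ] <- F[i, ] + colSums(dc[keep, , drop = FALSE] * (coef / r))
      }
    }
  }
  # reciprocal-space
  B <- 2 * pi * t(solve(cell))      # rows are reciprocal vectors
  axlen <- sqrt(rowSums(cell^2))
  m <- pmax(1L, as.integer(ceiling(kmax * axlen / (2 * pi))) + 1L)
  hs <- image_shifts(m)
  hs <- hs[rowSums(abs(hs)) > 0, , drop = FALSE]
  kv <- hs %*% B
  k2 <- rowSums(kv^2)
  keep <- k2 <= kmax^2
  kv <- kv[keep, , drop = FALSE]; k2 <- k2[keep]
  if (nrow(kv) > 0) {
    th <- pos %*% t(kv)             # n x nk phases
    C <- as.numeric(q %*% cos(th))
    D <- as.numeric(q %*% sin(th))
    A <- exp(-k2 / (4 * alpha^2)) / k2
    E <- E + ke * (2 * pi / V) * sum(A * (C^2 + D^2))
    if (forces) {
      for (i in seq_len(n)) {
        coef <- ke * (4 * pi / V) * q[i] * A *
          (sin(th[i, ]) * C - cos(th[i, ]) * D)
        F[i, ] <- F[i, ] + colSums(kv * coef)
      }
    }
  }
  # self
  E <- E - ke * alpha / sqrt(pi) * sum(q^2)
  out <- list(energy = E)
  if (forces) out$forces <- F
  out
}

erfc_ <- function(x) 2 * stats::pnorm(x * sqrt(2), lower.tail = FALSE)

#' Ewald electrostatics as a Calculator
#' @param settings An [ewald_settings()] list.
#' @export
ewald_calculator <- function(settings = ewald_settings()) {
  structure(list(settings = settings),
            class = c("csp_calc_ewald", "csp_calculator"),
            capabilities = c(energy = TRUE, forces = TRUE, stress = FALSE,
                             analytic_hessian = FALSE, charges = TRUE))
}

#' @rdname calc_eval
#' @export
calc_eval.csp_calc_ewald <- function(calc, geom, forces = FALSE, stress = FALSE) {
  stopifnot(inherits(geom, "csp_crystal"))
  out <- ewald_energy(geom, settings = calc$settings, forces = forces)
  if (stress) out$stress <- numerical_stress(calc, geom)
  out
}

# ---------------------------------------------------------------------------
# dispersion

#' Two-body dispersion energy with Becke-Johnson-style damping
#'
#' `E = -sum_pairs C6 / (r^6 + r0^6)` over pairs within the cutoff (periodic
#' images included for crystals). Used during optimization; the three-body
#' term is applied only as a post-optimization single point.
#'
#' @param geom Geometry (crystal, molecule or n-mer).
#' @param params List with `C6` (named per sorted species pair, eV A^6),
#'   `r0` (damping radius, A) and optional `cutoff` (A, default 15).
#' @return Energy in eV.
#' @export
dispersion_two_body <- function(geom, params) {
  cutoff <- params$cutoff %||% 15
  pl <- pair_list(geom, cutoff)
  if (length(pl$r) == 0) return(0)
  keys <- pair_key_vec(pl$symbols[pl$i], pl$symbols[pl$j])
  c6 <- vapply(keys, function(k) {
    v <- params$C6[[k]] %||% params$C6[["default"]]
    if (is.null(v)) stop("missing C6 for pair ", k)
    v
  }, 0)
  if (any(c6 < 0)) stop("C6 must be >= 0")
  -0.5 * sum(c6 / (pl$r^6 + (params$r0 %||% 0)^6))
}

#' Axilrod-Teller-Muto three-body dispersion correction
#'
#' `E = sum_triples C9 (3 cos t_i cos t_j cos t_k + 1) / (r_ij r_jk r_ki)^3`,
#' evaluated as a single-point correction on final geometries. For crystals,
#' triples are formed from the cell sites with minimum-image separations.
#'
#' @param geom Geometry.
#' @param params List with `C9` (scalar, or named per species triple, eV A^9)
#'   and optional `cutoff` (A, default 10).
#' @return Energy in eV.
#' @export
atm_three_body <- function(geom, params) {
  cutoff <- params$cutoff %||% 10
  at <- as_atoms(geom)
  pos <- at$positions
  n <- nrow(pos)
  if (n < 3) return(0)
  dvec <- function(i, j) {
    d <- pos[j, ] - pos[i, ]
    if (inherits(geom, "csp_crystal")) {
      df <- coords_convert(geom$lattice, matrix(d, 1, 3), "cart_to_frac")
      d <- as.numeric(min_image_cart(as.matrix(geom$lattice), df))
    }
    d
  }
  E <- 0
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    rij <- dvec(i, j); rjk <- dvec(j, k); rki <- dvec(k, i)
    dij <- sqrt(sum(rij^2)); djk <- sqrt(sum(rjk^2)); dki <- sqrt(sum(rki^2))
    if (dij > cutoff || djk > cutoff || dki > cutoff) next
    ci <- -sum(rij * rki) / (dij * dki)   # angle at i between j and k
    cj <- -sum(rjk * rij) / (djk * dij)
    ck <- -sum(rki * rjk) / (dki * djk)
    c9 <- if (is.numeric(params$C9) && length(params$C9) == 1) params$C9 else {
      key <- paste(sort(at$symbols[c(i, j, k)]), collapse = "-")
      v <- params$C9[[key]] %||% params$C9[["default"]]
      if (is.null(v)) stop("missing C9 for triple ", key)
      v
    }
    if (c9 < 0) stop("C9 must be >= 0")
    E <- E + c9 * (3 * ci * cj * ck + 1) / (dij * djk * dki)^3
  }
  E
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Sum of calculators
#'
#' Combines component models (e.g. pair potential + Ewald + two-body
#' dispersion) into one Calculator; energies, forces and stresses add.
#'
#' @param ... Calculator objects.
#' @export
composite_calculator <- function(...) {
  parts <- list(...)
  caps <- Reduce(`&`, lapply(parts, calc_capabilities))
  caps["energy"] <- TRUE
  structure(list(parts = parts),
            class = c("csp_calc_composite", "csp_calculator"),
            capabilities = caps)
}

#' @rdname calc_eval
#' @export
calc_eval.csp_calc_composite <- function(calc, geom, forces = FALSE, stress = FALSE) {
  res <- lapply(calc$parts, function(p) {
    caps <- calc_capabilities(p)
    out <- calc_eval(p, geom, forces = forces && caps["forces"],
                     stress = stress && caps["stress"])
    if (forces && is.null(out$forces)) out$forces <- numerical_forces(p, geom)
    if (stress && is.null(out$stress)) out$stress <- numerical_stress(p, geom)
    out
  })
  out <- list(energy = sum(vapply(res, function(r) r$energy, 0)))
  if (forces) out$forces <- Reduce(`+`, lapply(res, function(r) r$forces))
  if (stress) out$stress <- Reduce(`+`, lapply(res, function(r) r$stress))
  out
}

#' @rdname calc_hessian
#' @export
calc_hessian.csp_calc_composite <- function(calc, geom) {
  Reduce(`+`, lapply(calc$parts, calc_hessian, geom = geom))
}

#' Harmonic bond-spring calculator
#'
#' `E = sum_bonds k/2 (r - r0)^2` over the geometry's bond list, with rest
#' lengths captured from a reference geometry at construction. Holds
#' molecules together in flexible-molecule teachers
#' (`pair_potential(..., intermolecular_only = TRUE) + bond_calculator(...)`).
#'
#' @param reference A `csp_molecule` or `csp_nmer` providing bonds and rest
#'   lengths; omit it (and set `r0`) to read the bond list from each
#'   evaluated geometry instead, with a common rest length.
#' @param k Spring constant, eV/A^2 (default 30, a typical covalent
#'   stretch).
#' @param r0 Fixed rest length (A) used when no reference is given.
#' @export
bond_calculator <- function(reference = NULL, k = 30, r0 = NULL) {
  if (is.null(reference)) {
    stopifnot(!is.null(r0))
    bonds <- NULL
    r0v <- r0
  } else {
    at <- as_atoms(reference)
    bonds <- at$bonds
    r0v <- vapply(seq_len(nrow(bonds)), function(q) {
      sqrt(sum((at$positions[bonds[q, 1], ] - at$positions[bonds[q, 2], ])^2))
    }, 0)
  }
  structure(list(bonds = bonds, r0 = r0v, k = k),
            class = c("csp_calc_bond", "csp_calculator"),
            capabilities = c(energy = TRUE, forces = TRUE, stress = FALSE,
                             analytic_hessian = FALSE, charges = FALSE))
}

#' @rdname calc_eval
#' @export
calc_eval.csp_calc_bond <- function(calc, geom, forces = FALSE, stress = FALSE) {
  at <- as_atoms(geom)
  pos <- at$positions
  bonds <- calc$bonds
  if (is.null(bonds)) {
    if (inherits(geom, "csp_crystal")) {
      # periodic geometry: detect covalent bonds (with image shifts) on the fly
      bi <- attr(geom, "bond_images")
      if (is.null(bi)) bi <- attr(identify_molecules(geom), "bond_images")
      bonds <- do.call(rbind, lapply(bi, function(b) c(b$i, b$j)))
      if (is.null(bonds)) bonds <- matrix(integer(0), ncol = 2)
      shifts <- do.call(rbind, lapply(bi, function(b) b$shift))
    } else {
      bonds <- at$bonds
      shifts <- NULL
    }
  } else shifts <- NULL
  cellm <- if (inherits(geom, "csp_crystal")) as.matrix(geom$lattice) else NULL
  r0 <- if (length(calc$r0) == 1) rep(calc$r0, nrow(bonds)) else calc$r0
  E <- 0
  F <- matrix(0, nrow(pos), 3)
  for (q in seq_len(nrow(bonds))) {
    i <- bonds[q, 1]; j <- bonds[q, 2]
    d <- pos[j, ] - pos[i, ]
    if (!is.null(cellm)) {
      sh <- if (!is.null(shifts)) shifts[q, ] else {
        df <- coords_convert(geom$lattice, matrix(d, 1, 3), "cart_to_frac")
        -round(as.numeric(df))
      }
      d <- d + sh %*% cellm
      d <- as.numeric(d)
    }
    r <- sqrt(sum(d^2))
    E <- E + 0.5 * calc$k * (r - r0[q])^2
    if (forces) {
      f <- calc$k * (r - r0[q]) * d / r
      F[i, ] <- F[i, ] + f
      F[j, ] <- F[j, ] - f
    }
  }
  out <- list(energy = E)
  if (forces) out$forces <- F
  if (stress) out$stress <- numerical_stress(calc, geom)
  out
}

#' Volume-only equation-of-state calculator
#'
#' Energy depends on the cell volume alone through a third-order
#' Birch-Murnaghan form: zero forces, isotropic analytic stress, zero
#' Hessian. Combined with an Einstein calculator it yields a crystal whose
#' phonon frequencies are volume-independent (no thermal expansion).
#'
#' @param F0,V0,B0,B0p Birch-Murnaghan parameters (eV, A^3, eV/A^3, -).
#' @export
eos_calculator <- function(F0, V0, B0, B0p = 4) {
  structure(list(F0 = F0, V0 = V0, B0 = B0, B0p = B0p),
            class = c("csp_calc_eos", "csp_calculator"),
            capabilities = c(energy = TRUE, forces = TRUE, stress = TRUE,
                             analytic_hessian = TRUE, charges = FALSE))
}

#' @rdname calc_eval
#' @export
calc_eval.csp_calc_eos <- function(calc, geom, forces = FALSE, stress = FALSE) {
  stopifnot(inherits(geom, "csp_crystal"))
  V <- cell_volume(geom$lattice)
  out <- list(energy = birch_murnaghan(V, calc$F0, calc$V0, calc$B0, calc$B0p))
  if (forces) out$forces <- matrix(0, length(geom$species), 3)
  if (stress) {
    h <- V * 1e-6
    dEdV <- (birch_murnaghan(V + h, calc$F0, calc$V0, calc$B0, calc$B0p) -
               birch_murnaghan(V - h, calc$F0, calc$V0, calc$B0, calc$B0p)) /
      (2 * h)
    out$stress <- diag(dEdV, 3)
  }
  out
}

#' @rdname calc_hessian
#' @export
calc_hessian.csp_calc_eos <- function(calc, geom) {
  n <- nrow(geom_positions(geom))
  matrix(0, 3 * n, 3 * n)
}

#' Generic calculator from an energy function
#'
#' Wraps a plain `function(geom) -> eV` as a Calculator with numerical
#' derivatives; useful for custom teachers in tests and examples.
#' @param fn Energy function.
#' @export
function_calculator <- function(fn) {
  structure(list(fn = fn),
            class = c("csp_calc_fn", "csp_calculator"),
            capabilities = c(energy = TRUE, forces = FALSE, stress = FALSE,
                             analytic_hessian = FALSE, charges = FALSE))
}

#' @rdname calc_eval
#' @export
calc_eval.csp_calc_fn <- function(calc, geom, forces = FALSE, stress = FALSE) {
  out <- list(energy = calc$fn(geom))
  if (forces) out$forces <- numerical_forces(calc, geom)
  if (stress) out$stress <- numerical_stress(calc, geom)
  out
}
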