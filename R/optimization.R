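# Crystal relaxation (BFGS with backtracking; cell degrees of freedom via a
# symmetric strain so atomic and cell steps share one quasi-Newton state) and
# duplicate-structure removal.

#' Relaxation settings
#' @param rms_force_tol RMS atomic force convergence, eV/A (default 0.001).
#' @param max_steps Step budget (default 500).
#' @param mode `"variable_cell"`, `"fixed_volume_variable_cell"` or
#'   `"fixed_cell"`.
#' @param external_pressure Pressure entering the objective as `+ p V`,
#'   eV/A^3 (default 0).
#' @param stress_tol Convergence on `max |stress + p I|`, eV/A^3 (default
#'   1e-6, tight enough that soft van der Waals cells relax to ~1e-3 A).
#' @export
relax_settings <- function(rms_force_tol = 0.001, max_steps = 500,
                           mode = c("variable_cell",
                                    "fixed_volume_variable_cell",
                                    "fixed_cell"),
                           external_pressure = 0,
                           stress_tol = 1e-6) {
  mode <- match.arg(mode)
  stopifnot(rms_force_tol > 0)
  list(rms_force_tol = rms_force_tol, max_steps = max_steps, mode = mode,
       external_pressure = external_pressure, stress_tol = stress_tol)
}

#' Relax a crystal structure
#'
#' Minimises `E + p V` by BFGS with a backtracking (Armijo) line search over
#' atomic positions and, in the cell modes, a symmetric strain. In
#' `fixed_volume_variable_cell` mode the isotropic strain component is
#' projected out and the determinant of the cell is preserved exactly
#' (renormalised each step); shape and positions relax.
#'
#' @param structure A `csp_crystal`.
#' @param calculator Forces (and stress, for cell modes) provider.
#' @param settings A [relax_settings()].
#' @return List: `structure` (relaxed), `energy` (eV), `converged`,
#'   `n_steps`, `rms_force`, `trajectory` (data.frame of E and RMS force per
#'   accepted step).
#' @export
relax <- function(structure, calculator, settings = relax_settings()) {
  mode <- settings$mode
  cell0 <- as.matrix(structure$lattice)
  V0 <- cell_volume(cell0)
  n <- length(structure$species)
  cellmode <- mode != "fixed_cell"

  build <- function(v) {
    g <- structure
    if (cellmode) {
      eps <- matrix(0, 3, 3)
      eps[upper.tri(eps, diag = TRUE)] <- v[1:6]
      eps <- (eps + t(eps)) / 2
      cell <- cell0 %*% (diag(3) + eps)
      if (mode == "fixed_volume_variable_cell") {
        cell <- cell * (V0 / abs(det(cell)))^(1 / 3)
      }
      g$lattice <- lattice(cell)
      g$frac_coords <- matrix(v[-(1:6)], ncol = 3) %% 1
    } else {
      g$frac_coords <- matrix(v, ncol = 3) %% 1
    }
    g
  }
  objective <- function(v) {
    g <- build(v)
    e <- calc_eval(calculator, g)$energy
    e + settings$external_pressure * cell_volume(g$lattice)
  }
  gradient <- function(v) {
    g <- build(v)
    res <- calc_eval(calculator, g, forces = TRUE, stress = cellmode)
    if (cellmode && is.null(res$stress)) res$stress <- numerical_stress(calculator, g)
    cell <- as.matrix(g$lattice)
    gfrac <- -(res$forces %*% t(cell))
    if (!cellmode) return(list(grad = as.numeric(gfrac), res = res, geom = g))
    V <- cell_volume(cell)
    sg <- V * (res$stress + diag(settings$external_pressure, 3))
    if (mode == "fixed_volume_variable_cell") {
      sg <- sg - diag(sum(diag(sg)) / 3, 3)
    }
    # pack symmetric strain gradient: off-diagonals act twice
    gs <- c(sg[1, 1], 2 * sg[1, 2], sg[2, 2], 2 * sg[1, 3], 2 * sg[2, 3],
            sg[3, 3])
    list(grad = c(gs, as.numeric(gfrac)), res = res, geom = g)
  }

  v <- if (cellmode) c(rep(0, 6), as.numeric(structure$frac_coords))
       else as.numeric(structure$frac_coords)
  nv <- length(v)
  B <- diag(nv)                 # inverse-Hessian approximation
  f0 <- objective(v)
  gr <- gradient(v)
  traj <- list(data.frame(step = 0L, energy = gr$res$energy,
                          rms_force = rms_force(gr$res$forces)))
  conv <- function(res) {
    ok <- rms_force(res$forces) <= settings$rms_force_tol
    if (cellmode && ok) {
      s <- res$stress + diag(settings$external_pressure, 3)
      if (mode == "fixed_volume_variable_cell") {
        s <- s - diag(sum(diag(s)) / 3, 3)
      }
      ok <- max(abs(s)) <= settings$stress_tol
    }
    ok
  }
  step <- 0L
  converged <- conv(gr$res)
  while (!converged && step < settings$max_steps) {
    step <- step + 1L
    p <- -as.numeric(B %*% gr$grad)
    gtp <- sum(gr$grad * p)
    if (gtp >= 0) { B <- diag(nv); p <- -gr$grad; gtp <- sum(gr$grad * p) }
    alpha <- 1
    maxmove <- 0.2
    # cap the largest fractional/strain move
    pmax_ <- max(abs(p))
    if (pmax_ * alpha > maxmove) alpha <- maxmove / pmax_
    accepted <- FALSE
    for (ls in 1:30) {
      vt <- v + alpha * p
      ft <- objective(vt)
      if (ft <= f0 + 1e-4 * alpha * gtp) { accepted <- TRUE; break }
      alpha <- alpha / 2
    }
    if (!accepted) break
    grt <- gradient(vt)
    s <- vt - v
    y <- grt$grad - gr$grad
    sy <- sum(s * y)
    if (sy > 1e-12) {
      rho <- 1 / sy
      I_ <- diag(nv)
      B <- (I_ - rho * outer(s, y)) %*% B %*% (I_ - rho * outer(y, s)) +
        rho * outer(s, s)
    }
    v <- vt; f0 <- ft; gr <- grt
    traj[[length(traj) + 1]] <- data.frame(step = step, energy = gr$res$energy,
                                           rms_force = rms_force(gr$res$forces))
    converged <- conv(gr$res)
  }
  out_struct <- build(v)
  if (!converged) {
    warning("relaxation not converged: RMS force = ",
            signif(rms_force(gr$res$forces), 3), " eV/A after ", step, " steps")
  }
  list(structure = out_struct, energy = gr$res$energy, converged = converged,
       n_steps = step, rms_force = rms_force(gr$res$forces),
       trajectory = do.call(rbind, traj))
}

rms_force <- function(f) sqrt(mean(f^2))

# ---------------------------------------------------------------------------
# structure matching / duplicate removal

#' Matching tolerances for duplicate detection
#' @param stol Site RMS tolerance, Angstrom (default 0.2).
#' @param ltol Fractional lattice-length tolerance (default 0.2).
#' @param angle_tol Angle tolerance, degrees (default 5).
#' @param symprec Symmetrisation tolerance, Angstrom (default 0.2).
#' @export
match_tolerances <- function(stol = 0.2, ltol = 0.2, angle_tol = 5,
                             symprec = 0.2) {
  stopifnot(stol > 0, ltol > 0, angle_tol > 0, symprec > 0)
  list(stol = stol, ltol = ltol, angle_tol = angle_tol, symprec = symprec)
}

# Krivy-Gruber Niggli reduction; returns reduced cell and the integer
# transformation M with cell_red = M %*% cell.
niggli_reduce <- function(cell, eps = 1e-5) {
  M <- diag(3)
  cell <- as.matrix(cell)
  get_g <- function(C) {
    A <- sum(C[1, ]^2); B <- sum(C[2, ]^2); G <- sum(C[3, ]^2)
    xi <- 2 * sum(C[2, ] * C[3, ]); eta <- 2 * sum(C[1, ] * C[3, ])
    zeta <- 2 * sum(C[1, ] * C[2, ])
    c(A, B, G, xi, eta, zeta)
  }
  for (iter in 1:200) {
    C <- M %*% cell
    g <- get_g(C)
    A <- g[1]; B <- g[2]; Cg <- g[3]; xi <- g[4]; eta <- g[5]; zeta <- g[6]
    if (A > B + eps || (abs(A - B) < eps && abs(xi) > abs(eta) + eps)) {
      M <- matrix(c(0, -1, 0, -1, 0, 0, 0, 0, -1), 3, 3, byrow = TRUE) %*% M
      next
    }
    if (B > Cg + eps || (abs(B - Cg) < eps && abs(eta) > abs(zeta) + eps)) {
      M <- matrix(c(-1, 0, 0, 0, 0, -1, 0, -1, 0), 3, 3, byrow = TRUE) %*% M
      next
    }
    ppos <- (xi > eps) + (eta > eps) + (zeta > eps)
    nneg <- (xi < -eps) + (eta < -eps) + (zeta < -eps)
    if (!(ppos == 3 || (ppos == 0 && nneg >= 0))) {
      # make all angles acute or all non-acute
      i_ <- if (xi > eps) -1 else 1
      j_ <- if (eta > eps) -1 else 1
      k_ <- if (zeta > eps) -1 else 1
      if (i_ * j_ * k_ < 0) {
        if (abs(xi) < eps) i_ <- -j_ * k_
        else if (abs(eta) < eps) j_ <- -i_ * k_
        else k_ <- -i_ * j_
      }
      M <- diag(c(i_, j_, k_)) %*% M
      next
    }
    if (abs(xi) > B + eps ||
        (abs(B - xi) < eps && 2 * eta < zeta - eps) ||
        (abs(B + xi) < eps && zeta < -eps)) {
      s <- if (xi > 0) -1 else 1
      T <- diag(3); T[3, 2] <- s
      M <- T %*% M
      next
    }
    if (abs(eta) > A + eps ||
        (abs(A - eta) < eps && 2 * xi < zeta - eps) ||
        (abs(A + eta) < eps && zeta < -eps)) {
      s <- if (eta > 0) -1 else 1
      T <- diag(3); T[3, 1] <- s
      M <- T %*% M
      next
    }
    if (abs(zeta) > A + eps ||
        (abs(A - zeta) < eps && 2 * xi < eta - eps) ||
        (abs(A + zeta) < eps && eta < -eps)) {
      s <- if (zeta > 0) -1 else 1
      T <- diag(3); T[2, 1] <- s
      M <- T %*% M
      next
    }
    if (xi + eta + zeta + A + B < -eps ||
        (abs(xi + eta + zeta + A + B) < eps && 2 * (A + eta) + zeta > eps)) {
      T <- diag(3); T[3, 1] <- 1; T[3, 2] <- 1
      M <- T %*% M
      next
    }
    break
  }
  red <- M %*% cell
  if (det(red) < 0) { M <- -M; red <- -red }
  list(cell = red, M = M)
}

# reduce a structure: niggli cell + transformed fracs
reduce_structure <- function(s) {
  nr <- niggli_reduce(as.matrix(s$lattice))
  f <- s$frac_coords %*% solve(nr$M)
  crystal_structure(lattice(nr$cell), s$species, f, Z = s$Z)
}

# try to match structure B onto A (both reduced); returns best site RMS or Inf
match_rms <- function(A, B, ltol, angle_tol, early_stop = 0) {
  pa <- lattice_params(A$lattice); pb <- lattice_params(B$lattice)
  if (length(A$species) != length(B$species)) return(Inf)
  if (!identical(sort(A$species), sort(B$species))) return(Inf)
  cellA <- as.matrix(A$lattice)
  best <- Inf
  # lattice automorphism candidates: signed permutations mapping B's metric
  # onto A's within tolerance
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2),
                c(3, 2, 1))
  for (p in perms) for (s1 in c(-1, 1)) for (s2 in c(-1, 1)) for (s3 in c(-1, 1)) {
    P <- matrix(0, 3, 3)
    sg <- c(s1, s2, s3)
    for (k in 1:3) P[k, p[k]] <- sg[k]
    cellBp <- P %*% as.matrix(B$lattice)
    pbp <- lattice_params(lattice_abs(cellBp))
    if (any(abs(pbp[1:3] - pa[1:3]) / pa[1:3] > ltol)) next
    if (any(abs(pbp[4:6] - pa[4:6]) > angle_tol)) next
    fB <- (B$frac_coords %*% solve(P)) %% 1
    r <- best_translation_rms(A$species, A$frac_coords, B$species, fB, cellA,
                              early_stop)
    best <- min(best, r)
    if (best <= early_stop) return(best)
  }
  best
}

lattice_abs <- function(cell) {
  if (det(cell) < 0) cell <- -cell
  lattice(cell)
}

# best species-aware assignment RMS over candidate translations (every
# translation aligning a B site onto the first A site of its species, plus a
# coarse grid) with local recentring refinement
best_translation_rms <- function(spA, fA, spB, fB, cell, early_stop = 0) {
  n <- nrow(fA)
  best <- Inf
  assign_rms <- function(t) {
    fBt <- sweep(fB, 2, -t)
    used <- logical(n)
    d2s <- numeric(n)
    disp <- matrix(0, n, 3)
    for (i in seq_len(n)) {
      d <- fBt - matrix(fA[i, ], n, 3, byrow = TRUE)
      d <- d - round(d)
      dc <- d %*% cell
      dd <- rowSums(dc^2)
      dd[used | spB != spA[i]] <- Inf
      j <- which.min(dd)
      used[j] <- TRUE
      d2s[i] <- dd[j]
      disp[i, ] <- d[j, ]
    }
    list(rms = sqrt(mean(d2s)), mean_disp = colMeans(disp))
  }
  cands <- list()
  # t such that fB + t aligns site j onto A's first site of that species
  for (j in which(spB == spA[1])) cands[[length(cands) + 1]] <- fA[1, ] - fB[j, ]
  grid <- seq(0.125, 0.875, by = 0.25)
  for (tx in grid) for (ty in grid) for (tz in grid) {
    cands[[length(cands) + 1]] <- c(tx, ty, tz)
  }
  for (t in cands) {
    r <- assign_rms(t)
    t2 <- t
    for (it in 1:6) {
      t2 <- t2 - r$mean_disp
      r2 <- assign_rms(t2)
      if (r2$rms >= r$rms - 1e-12) break
      r <- r2
    }
    best <- min(best, r$rms)
    if (best <= early_stop) return(best)
  }
  best
}

#' Do two crystal structures match?
#'
#' Both lattices are Niggli-reduced; candidate lattice correspondences whose
#' lengths agree within `ltol` (fractional) and angles within `angle_tol` are
#' scanned, and for each the best species-aware site assignment under an
#' origin-translation search is computed. A match requires site RMS <=
#' `stol`.
#'
#' @param a,b `csp_crystal` objects.
#' @param tolerances A [match_tolerances()].
#' @return Logical.
#' @export
structures_match <- function(a, b, tolerances = match_tolerances()) {
  ra <- reduce_structure(a); rb <- reduce_structure(b)
  r1 <- match_rms(ra, rb, tolerances$ltol, tolerances$angle_tol,
                  early_stop = tolerances$stol * 0.999)
  if (r1 > tolerances$stol) return(FALSE)
  r2 <- match_rms(rb, ra, tolerances$ltol, tolerances$angle_tol,
                  early_stop = tolerances$stol * 0.999)
  r2 <= tolerances$stol
}

#' Remove duplicate structures
#'
#' Pairwise matching by [structures_match()] with transitive closure; the
#' representative of each cluster is its lowest-energy member when `energies`
#' are supplied, else the first seen.
#'
#' @param structures List of `csp_crystal`.
#' @param tolerances A [match_tolerances()].
#' @param energies Optional numeric energies (eV), same length.
#' @return List: `unique` (representative structures), `cluster` (integer
#'   cluster id per input), `representative` (index of each cluster's
#'   representative).
#' @export
deduplicate <- function(structures, tolerances = match_tolerances(),
                        energies = NULL) {
  n <- length(structures)
  stopifnot(n >= 1)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (find(i) == find(j)) next
    if (structures_match(structures[[i]], structures[[j]], tolerances)) {
      parent[find(j)] <- find(i)
    }
  }
  roots <- vapply(seq_len(n), find, 0L)
  ids <- match(roots, unique(roots))
  reps <- vapply(seq_len(max(ids)), function(k) {
    members <- which(ids == k)
    if (!is.null(energies)) members[which.min(energies[members])]
    else members[1]
  }, 0L)
  list(unique = structures[reps], cluster = ids, representative = reps)
}
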