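# Harmonic phonons from analytic or finite-displacement force constants,
# vibrational free energy, harmonic Gibbs energy, Birch-Murnaghan EOS
# fitting, the quasi-harmonic volume scan, and heat capacity.

#' Build a supercell
#'
#' @param crystal A `csp_crystal`.
#' @param reps Integer vector of multiplicities (n1, n2, n3).
#' @return A `csp_crystal` with attributes `"base_index"` (primitive atom of
#'   each supercell site) and `"offset"` (integer cell offset per site).
#' @export
make_supercell <- function(crystal, reps) {
  reps <- as.integer(reps)
  cell <- as.matrix(crystal$lattice)
  n <- length(crystal$species)
  sp <- character(0); fr <- NULL; base <- integer(0); off <- NULL
  for (i3 in 0:(reps[3] - 1)) for (i2 in 0:(reps[2] - 1)) for (i1 in 0:(reps[1] - 1)) {
    o <- c(i1, i2, i3)
    fr <- rbind(fr, sweep(crystal$frac_coords, 2, -o) /
                  matrix(reps, n, 3, byrow = TRUE))
    sp <- c(sp, crystal$species)
    base <- c(base, seq_len(n))
    off <- rbind(off, matrix(o, n, 3, byrow = TRUE))
  }
  sc <- crystal_structure(lattice(diag(reps) %*% cell), sp, fr,
                          Z = crystal$Z * prod(reps),
                          charges = rep(crystal$charges, prod(reps)))
  attr(sc, "base_index") <- base
  attr(sc, "offset") <- off
  attr(sc, "reps") <- reps
  sc
}

#' Force constants of a crystal
#'
#' Builds the smallest supercell whose lattice vectors all reach
#' `min_supercell_length`, then computes the second-derivative block
#' coupling the reference-cell atoms to every supercell atom, either from
#' the calculator's analytic Hessian or by central finite displacements
#' (default 0.005 A). The translational acoustic sum rule is enforced on the
#' self blocks.
#'
#' @param structure A relaxed `csp_crystal` (a warning is issued if the RMS
#'   force exceeds 0.001 eV/A).
#' @param calculator Energy/force provider.
#' @param method `"auto"` (analytic when available), `"analytic"` or
#'   `"finite_displacement"`.
#' @param min_supercell_length Minimum supercell vector length, A (default 10).
#' @param displacement Finite-displacement amplitude, A (default 0.005).
#' @param asr Enforce the translational acoustic sum rule on the self blocks
#'   (default TRUE; disable for models that deliberately break translation
#'   invariance, e.g. site-tethered Einstein crystals).
#' @return Object of class `csp_forceconstants`: fields `matrix`
#'   (3n x 3N, eV/A^2), `supercell`, `primitive`, `masses`.
#' @export
hessian <- function(structure, calculator, method = c("auto", "analytic",
                                                      "finite_displacement"),
                    min_supercell_length = 10, displacement = 0.005,
                    asr = TRUE) {
  method <- match.arg(method)
  caps <- calc_capabilities(calculator)
  if (method == "auto") {
    method <- if (isTRUE(caps[["analytic_hessian"]])) "analytic"
              else "finite_displacement"
  }
  if (method == "analytic" && !isTRUE(caps[["analytic_hessian"]])) {
    stop("calculator provides no analytic Hessian")
  }
  if (method == "finite_displacement" && !isTRUE(caps[["forces"]])) {
    stop("calculator provides neither analytic Hessian nor forces")
  }
  res0 <- calc_eval(calculator, structure, forces = TRUE)
  if (rms_force(res0$forces) > 0.0011) {
    warning("structure not relaxed (RMS force ",
            signif(rms_force(res0$forces), 3), " eV/A)")
  }
  axlen <- sqrt(rowSums(as.matrix(structure$lattice)^2))
  reps <- pmax(1L, as.integer(ceiling(min_supercell_length / axlen)))
  sc <- make_supercell(structure, reps)
  n <- length(structure$species)
  N <- length(sc$species)
  if (method == "analytic") {
    Hfull <- calc_hessian(calculator, sc)
    H <- Hfull[1:(3 * n), , drop = FALSE]   # rows: cell-0 atoms (first block)
  } else {
    pos0 <- geom_positions(sc)
    H <- matrix(0, 3 * n, 3 * N)
    for (i in seq_len(n)) for (a in 1:3) {
      pp <- pos0; pp[i, a] <- pp[i, a] + displacement
      fp <- calc_eval(calculator, geom_set_positions(sc, pp), forces = TRUE)$forces
      pp[i, a] <- pos0[i, a] - displacement
      fm <- calc_eval(calculator, geom_set_positions(sc, pp), forces = TRUE)$forces
      H[3 * (i - 1) + a, ] <- -as.numeric(t(fp - fm)) / (2 * displacement)
    }
  }
  # acoustic sum rule: self block absorbs minus the row sums
  if (asr) for (i in seq_len(n)) for (a in 1:3) {
    row <- 3 * (i - 1) + a
    for (b in 1:3) {
      cols <- seq(b, 3 * N, by = 3)
      excess <- sum(H[row, cols])
      selfcol <- 3 * (i - 1) + b
      H[row, selfcol] <- H[row, selfcol] - excess
    }
  }
  structure(list(matrix = H, supercell = sc, primitive = structure,
                 masses = structure$elements$mass, method = method,
                 displacement = displacement),
            class = "csp_forceconstants")
}

#' Phonon frequencies at a q-point
#'
#' Builds the mass-weighted dynamical matrix by Fourier transform of the
#' force constants (minimum-image cell offsets, weight-split on ties) and
#' diagonalises it. Negative eigenvalues are reported as negative
#' frequencies (imaginary modes).
#'
#' @param fc A `csp_forceconstants`.
#' @param qpoint Fractional reciprocal coordinates of the primitive cell.
#' @return Numeric vector of 3n frequencies in rad/s, ascending (negative =
#'   imaginary).
#' @export
phonon_frequencies <- function(fc, qpoint) {
  dyn_frequencies(fc_terms(fc), qpoint)
}

# q-independent Fourier bookkeeping: one term per (row atom, supercell atom)
# with its minimum-image offsets (ties split) and force-constant block
fc_terms <- function(fc) {
  n <- length(fc$primitive$species)
  N <- length(fc$supercell$species)
  reps <- attr(fc$supercell, "reps")
  base <- attr(fc$supercell, "base_index")
  off <- attr(fc$supercell, "offset")
  fr <- fc$primitive$frac_coords
  cell <- as.matrix(fc$primitive$lattice)
  ms <- image_shifts(c(1, 1, 1))
  terms <- list()
  for (j in seq_len(N)) {
    kp <- base[j]
    Ls <- ms * matrix(reps, nrow(ms), 3, byrow = TRUE) +
      matrix(off[j, ], nrow(ms), 3, byrow = TRUE)
    cols <- (3 * (j - 1) + 1):(3 * j)
    tcols <- (3 * (kp - 1) + 1):(3 * kp)
    for (i in seq_len(n)) {
      rows <- (3 * (i - 1) + 1):(3 * i)
      blk <- fc$matrix[rows, cols]
      if (all(blk == 0)) next
      dmat <- (Ls + matrix(fr[kp, ] - fr[i, ], nrow(Ls), 3, byrow = TRUE)) %*% cell
      d2 <- rowSums(dmat^2)
      keep <- which(d2 <= min(d2) + 1e-8)
      terms[[length(terms) + 1]] <- list(rows = rows, tcols = tcols,
                                         blk = blk,
                                         Ls = Ls[keep, , drop = FALSE])
    }
  }
  list(n = n, masses = fc$masses, terms = terms)
}

dyn_frequencies <- function(tm, qpoint) {
  n <- tm$n
  D <- matrix(0 + 0i, 3 * n, 3 * n)
  for (t in tm$terms) {
    phase <- sum(exp(2i * pi * (t$Ls %*% qpoint))) / nrow(t$Ls)
    D[t$rows, t$tcols] <- D[t$rows, t$tcols] + t$blk * phase
  }
  mw <- 1 / sqrt(rep(tm$masses, each = 3))
  D <- D * outer(mw, mw)
  D <- (D + Conj(t(D))) / 2
  ev <- eigen(D, symmetric = TRUE, only.values = TRUE)$values
  ev <- rev(ev)                       # ascending
  sign(ev) * sqrt(abs(ev)) * csp_constants$freq_factor
}

#' Phonon spectrum on a Gamma-centred q-mesh
#'
#' @param fc A `csp_forceconstants`.
#' @param mesh Integer mesh (default `c(8, 8, 8)`); uniform weights.
#' @return Object of class `csp_phonon_spectrum`: `qpoints` (fractional),
#'   `weights` (sum to 1), `frequencies` (matrix, rows = q-points, rad/s),
#'   `n_imaginary`.
#' @export
phonon_spectrum <- function(fc, mesh = c(8, 8, 8)) {
  mesh <- as.integer(mesh)
  qs <- as.matrix(expand.grid((0:(mesh[1] - 1)) / mesh[1],
                              (0:(mesh[2] - 1)) / mesh[2],
                              (0:(mesh[3] - 1)) / mesh[3]))
  tm <- fc_terms(fc)
  freqs <- t(apply(qs, 1, function(q) dyn_frequencies(tm, q)))
  structure(list(qpoints = qs, weights = rep(1 / nrow(qs), nrow(qs)),
                 frequencies = freqs,
                 n_imaginary = sum(freqs < -imag_tol())),
            class = "csp_phonon_spectrum")
}

# frequency below which a mode counts as a numerical zero (rad/s)
imag_tol <- function() 1e-4 * csp_constants$freq_factor

#' Harmonic vibrational free energy
#'
#' `F_vib = sum_q w_q sum_i [hbar w/2 + k_B T ln(1 - exp(-hbar w / k_B T))]`
#' per cell; at T = 0 this is the zero-point energy. Numerical-zero acoustic
#' modes are skipped.
#'
#' @param spectrum A `csp_phonon_spectrum`.
#' @param T Temperature, K.
#' @param imaginary `"strict"` (error when imaginary modes are present) or
#'   `"drop"` (exclude them).
#' @return F_vib in eV per cell.
#' @export
f_vib <- function(spectrum, T, imaginary = c("strict", "drop")) {
  imaginary <- match.arg(imaginary)
  tol <- imag_tol()
  if (spectrum$n_imaginary > 0 && imaginary == "strict") {
    stop("imaginary modes present (", spectrum$n_imaginary, ")")
  }
  kB <- csp_constants$k_B; hbar <- csp_constants$hbar
  total <- 0
  for (iq in seq_len(nrow(spectrum$frequencies))) {
    w <- spectrum$frequencies[iq, ]
    w <- w[w > tol]
    hw <- hbar * w
    term <- hw / 2
    if (T > 0) term <- term + kB * T * log(1 - exp(-hw / (kB * T)))
    total <- total + spectrum$weights[iq] * sum(term)
  }
  total
}

#' Harmonic-approximation Gibbs energy point
#'
#' `G = E_latt + F_vib(T) + p V`.
#'
#' @param E_latt Static lattice energy, eV/cell.
#' @param spectrum A `csp_phonon_spectrum`.
#' @param T Temperature, K.
#' @param p Pressure, eV/A^3 (default 0).
#' @param V Cell volume, A^3.
#' @param ... Passed to [f_vib()].
#' @return One-row tibble: E_latt, F_vib, T, p, V, G.
#' @export
gibbs_ha <- function(E_latt, spectrum, T, p = 0, V, ...) {
  Fv <- f_vib(spectrum, T, ...)
  tibble::tibble(E_latt = E_latt, F_vib = Fv, T = T, p = p, V = V,
                 G = E_latt + Fv + p * V)
}

#' Birch-Murnaghan (third-order) energy-volume model
#' @param V Volumes, A^3.
#' @param F0,V0,B0,B0p Parameters: energy minimum (eV), equilibrium volume
#'   (A^3), bulk modulus (eV/A^3), pressure derivative (dimensionless).
#' @export
birch_murnaghan <- function(V, F0, V0, B0, B0p) {
  x <- (V0 / V)^(2 / 3)
  F0 + 9 * V0 * B0 / 16 * ((x - 1)^3 * B0p + (x - 1)^2 * (6 - 4 * x))
}

#' Fit the third-order Birch-Murnaghan equation of state
#'
#' @param volumes Volumes, A^3 (>= 5 points bracketing a minimum).
#' @param free_energies Energies, eV.
#' @return List: `F0`, `V0`, `B0`, `B0p`, `rms_residual`; error of class
#'   `csp_fit_failure` when the data contain no interior minimum.
#' @export
fit_birch_murnaghan <- function(volumes, free_energies) {
  stopifnot(length(volumes) == length(free_energies))
  if (length(volumes) < 5) stop("need >= 5 points for an EOS fit")
  o <- order(volumes)
  V <- volumes[o]; F_ <- free_energies[o]
  imin <- which.min(F_)
  if (imin == 1 || imin == length(V)) {
    cond <- structure(class = c("csp_fit_failure", "error", "condition"),
                      list(message = "no interior minimum in the E-V data",
                           call = sys.call()))
    stop(cond)
  }
  # quadratic starting guess around the minimum
  qf <- stats::lm(F_ ~ V + I(V^2))
  a2 <- stats::coef(qf)[[3]]; a1 <- stats::coef(qf)[[2]]
  V0s <- -a1 / (2 * a2)
  if (!is.finite(V0s) || V0s <= min(V) || V0s >= max(V)) V0s <- V[imin]
  B0s <- max(2 * a2 * V0s, 1e-4)
  th0 <- c(min(F_), V0s, B0s, 4)
  obj <- function(th) {
    r <- birch_murnaghan(V, th[1], th[2], th[3], th[4]) - F_
    sum(r^2)
  }
  fit <- stats::optim(th0, obj, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-15))
  fit <- stats::optim(fit$par, obj, method = "BFGS",
                      control = list(maxit = 2000, reltol = 1e-15,
                                     parscale = abs(th0) + 1e-3))
  th <- fit$par
  list(F0 = th[1], V0 = th[2], B0 = th[3], B0p = th[4],
       rms_residual = sqrt(obj(th) / length(V)))
}

#' Quasi-harmonic volume scan
#'
#' After relaxing without external pressure, the cell volume is scaled by
#' each factor, a fixed-volume variable-cell relaxation is run, force
#' constants and the phonon spectrum are computed, and
#' `F(T, V) = U(V) + F_vib(T, V)`. Per temperature the F-V points are fitted
#' to the Birch-Murnaghan form: `G(T, p)` is the minimum of the fitted curve
#' plus `p V`, `V(T)` the argmin. Volume points with imaginary modes are
#' dropped (logged); fewer than 5 survivors is an error.
#'
#' @param structure A `csp_crystal`, pre-relaxed at p = 0 (relaxed internally
#'   otherwise).
#' @param calculator Energy model.
#' @param volume_factors Volume scale factors (default `seq(0.95, 1.15,
#'   by = 0.0125)`, 17 points).
#' @param T_list Temperatures, K.
#' @param p External pressure, eV/A^3 (default 0).
#' @param mesh q-mesh (default `c(8, 8, 8)`).
#' @param min_supercell_length Passed to [hessian()] (default 10 A).
#' @param relax_first Relax the input at p = 0 before scanning (default TRUE).
#' @param asr Passed to [hessian()] (default TRUE).
#' @param dT_cp Temperature step for the internal Cp grid, K (default 10).
#' @return Object of class `csp_thermo_curve`: `points` (tibble of T, V, U,
#'   F_vib, F), `eos` (per-T fit parameters), `summary` (tibble of T, G, V,
#'   Cp), `dropped` (volume factors dropped for imaginary modes).
#' @export
qha <- function(structure, calculator,
                volume_factors = seq(0.95, 1.15, by = 0.0125),
                T_list = c(0, 300), p = 0, mesh = c(8, 8, 8),
                min_supercell_length = 10, relax_first = TRUE, asr = TRUE,
                dT_cp = 10) {
  if (relax_first) {
    structure <- relax(structure, calculator,
                       relax_settings(mode = "variable_cell"))$structure
  }
  cell0 <- as.matrix(structure$lattice)
  rows <- list(); dropped <- numeric(0)
  spectra <- list(); Us <- numeric(0); Vs <- numeric(0)
  for (f in volume_factors) {
    g <- structure
    g$lattice <- lattice(cell0 * f^(1 / 3))
    r <- relax(g, calculator,
               relax_settings(mode = "fixed_volume_variable_cell"))
    fc <- hessian(r$structure, calculator,
                  min_supercell_length = min_supercell_length, asr = asr)
    sp <- phonon_spectrum(fc, mesh)
    if (sp$n_imaginary > 0) { dropped <- c(dropped, f); next }
    spectra[[length(spectra) + 1]] <- sp
    Us <- c(Us, r$energy)
    Vs <- c(Vs, cell_volume(r$structure$lattice))
  }
  if (length(Vs) < 5) stop("fewer than 5 volume points survived the scan")
  # temperatures needed: requested list plus a uniform Cp grid
  T_cp <- seq(min(T_list), max(max(T_list), min(T_list) + 4 * dT_cp),
              by = dT_cp)
  T_all <- sort(unique(c(T_list, T_cp)))
  pts <- list(); eos <- list(); Gs <- numeric(0); Vmins <- numeric(0)
  for (Tk in T_all) {
    Fv <- vapply(spectra, f_vib, 0, T = Tk)
    Ftot <- Us + Fv
    fit <- fit_birch_murnaghan(Vs, Ftot + p * Vs)
    eos[[length(eos) + 1]] <- c(T = Tk, F0 = fit$F0, V0 = fit$V0,
                                B0 = fit$B0, B0p = fit$B0p)
    Gs <- c(Gs, fit$F0)
    Vmins <- c(Vmins, fit$V0)
    pts[[length(pts) + 1]] <- tibble::tibble(T = Tk, V = Vs, U = Us,
                                             F_vib = Fv, F = Ftot)
  }
  cp_grid <- heat_capacity(Gs[match(T_cp, T_all)], T_cp)
  Cp_at <- stats::approx(T_cp, cp_grid, xout = T_all, rule = 2)$y
  structure(list(points = do.call(rbind, pts),
                 eos = tibble::as_tibble(do.call(rbind, eos)),
                 summary = tibble::tibble(T = T_all, G = Gs, V = Vmins,
                                          Cp = Cp_at),
                 requested_T = T_list, dropped = dropped,
                 pressure = p),
            class = "csp_thermo_curve")
}

#' Constant-pressure heat capacity from G(T)
#'
#' `Cp = -T d2G/dT2` by central differences on a uniform temperature grid
#' (nearest interior stencil at the endpoints, exact for quadratic G).
#'
#' @param G_of_T Gibbs energies, eV, on a uniform grid.
#' @param T_grid Temperatures, K (uniform, >= 5 points).
#' @return Cp(T) in eV/K.
#' @export
heat_capacity <- function(G_of_T, T_grid) {
  stopifnot(length(G_of_T) == length(T_grid), length(T_grid) >= 5)
  h <- diff(T_grid)
  if (max(abs(h - h[1])) > 1e-8 * max(abs(h))) stop("non-uniform T grid")
  h <- h[1]
  n <- length(T_grid)
  d2 <- numeric(n)
  for (i in 2:(n - 1)) d2[i] <- (G_of_T[i + 1] - 2 * G_of_T[i] + G_of_T[i - 1]) / h^2
  d2[1] <- (G_of_T[3] - 2 * G_of_T[2] + G_of_T[1]) / h^2
  d2[n] <- (G_of_T[n] - 2 * G_of_T[n - 1] + G_of_T[n - 2]) / h^2
  -T_grid * d2
}
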