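# Descriptor-regression surrogate: smooth radial-basis features of each
# atom's local environment (5 A cutoff by default), linear weights per
# element, trained on teacher energies (per-atom weighted) and optionally
# forces. Plays the role of the trainable interatomic potential behind the
# Calculator contract; prediction is a sum of atomic contributions.

#' Define a radial descriptor basis
#'
#' Features of atom i are, per neighbour element e, the sums over neighbours
#' j of that element of `exp(-(r_ij - mu_k)^2 / (2 delta^2)) * fcut(r_ij)`,
#' with `fcut(r) = (cos(pi r / cutoff) + 1)/2` vanishing smoothly at the
#' cutoff. Rotation-, translation- and permutation-invariant by construction;
#' an isolated atom has an all-zero feature vector.
#'
#' @param elements Character vector of element symbols the model supports.
#' @param cutoff Environment cutoff in Angstrom (default 5).
#' @param n_basis Number of radial Gaussians (default 8).
#' @return A descriptor definition (list).
#' @export
descriptor_basis <- function(elements, cutoff = 5, n_basis = 8) {
  mu <- seq(0.5, cutoff, length.out = n_basis)
  delta <- (mu[2] - mu[1])
  list(elements = sort(unique(elements)), cutoff = cutoff, n_basis = n_basis,
       mu = mu, delta = delta)
}

fcut <- function(r, rc) ifelse(r < rc, 0.5 * (cos(pi * r / rc) + 1), 0)

# neighbor list of a finite or periodic geometry within cutoff:
# list of data.frames per atom? Return flat: i, j, rvec, r (ordered pairs)
neighbor_list <- function(geom, cutoff) pair_list(geom, cutoff)

#' Atomic environment descriptors
#'
#' @param geom Geometry (molecule, n-mer or crystal).
#' @param basis A [descriptor_basis()].
#' @return N x (n_elements * n_basis) matrix of features, rows ordered as the
#'   geometry's atoms.
#' @export
descriptors <- function(geom, basis) {
  at <- as_atoms(geom)
  n <- length(at$symbols)
  ne <- length(basis$elements)
  X <- matrix(0, n, ne * basis$n_basis)
  nl <- neighbor_list(geom, basis$cutoff)
  if (length(nl$r) == 0) return(X)
  g <- outer(nl$r, basis$mu, function(r, m) exp(-(r - m)^2 / (2 * basis$delta^2))) *
    fcut(nl$r, basis$cutoff)
  eidx <- match(at$symbols[nl$j], basis$elements)
  if (anyNA(eidx)) stop("geometry contains elements outside the basis")
  for (k in seq_along(nl$r)) {
    cols <- ((eidx[k] - 1) * basis$n_basis + 1):(eidx[k] * basis$n_basis)
    X[nl$i[k], cols] <- X[nl$i[k], cols] + g[k, ]
  }
  X
}

# analytic gradient of all descriptors wrt atom positions:
# returns list over atoms m of dX/dx_m as (n_atoms*n_feat) sparse-ish arrays.
# For force rows we need d(sum_i w_{e(i)} . X_i)/dx_m; we build directly the
# Jacobian of the pooled per-element feature sums.
# pooled_jacobian returns, for each element block b and basis k, the matrix
# d(sum_{i in elem b'} X_i[b,k])/dx_{m,a}.
descriptor_force_design <- function(geom, basis) {
  at <- as_atoms(geom)
  n <- length(at$symbols)
  ne <- length(basis$elements)
  nf <- ne * basis$n_basis
  # weight layout: for atom of element e, weights w[e] over nf features + bias
  # energy E = sum_i w_{e(i)} . X_i + b_{e(i)}
  # dE/dx_{m,a} = sum over pairs; build J: (3n) x (ne * (nf+1)) design so that
  # F = -J %*% wfull
  J <- matrix(0, 3 * n, ne * (nf + 1))
  nl <- neighbor_list(geom, basis$cutoff)
  if (length(nl$r) == 0) return(J)
  eidx_j <- match(at$symbols[nl$j], basis$elements)
  eidx_i <- match(at$symbols[nl$i], basis$elements)
  rc <- basis$cutoff
  for (k in seq_along(nl$r)) {
    r <- nl$r[k]
    u <- nl$rvec[k, ] / r          # d r / d x_j = u, d r / d x_i = -u
    gk <- exp(-(r - basis$mu)^2 / (2 * basis$delta^2))
    fc <- 0.5 * (cos(pi * r / rc) + 1)
    dg <- gk * (-(r - basis$mu) / basis$delta^2) * fc +
      gk * (-0.5 * pi / rc * sin(pi * r / rc))
    # feature X_i[cols(e_j)] gains dg along r; weight block = element of i
    wblk <- (eidx_i[k] - 1) * (nf + 1)
    cols <- wblk + ((eidx_j[k] - 1) * basis$n_basis + 1):(eidx_j[k] * basis$n_basis)
    i <- nl$i[k]; j <- nl$j[k]
    for (a in 1:3) {
      J[3 * (j - 1) + a, cols] <- J[3 * (j - 1) + a, cols] + dg * u[a]
      J[3 * (i - 1) + a, cols] <- J[3 * (i - 1) + a, cols] - dg * u[a]
    }
  }
  J
}

#' Create a labeled sample
#'
#' @param geometry A `csp_molecule` or `csp_nmer`.
#' @param energy Teacher energy, eV.
#' @param forces Optional Nx3 teacher forces, eV/A.
#' @param charges,dipole Optional teacher partial charges (e) / dipole (e A).
#' @param teacher Name of the teacher that produced the labels.
#' @export
labeled_sample <- function(geometry, energy, forces = NULL, charges = NULL,
                           dipole = NULL, teacher = "teacher") {
  nat <- length(as_atoms(geometry)$symbols)
  if (!is.null(forces)) {
    forces <- matrix(as.numeric(forces), ncol = 3)
    stopifnot(nrow(forces) == nat)
  }
  structure(list(geometry = geometry, energy = as.numeric(energy),
                 forces = forces, charges = charges, dipole = dipole,
                 teacher = teacher, n_atoms = nat),
            class = "csp_sample")
}

#' Label geometries with a teacher calculator
#' @param geoms List of geometries.
#' @param teacher A calculator.
#' @param forces Include forces in the labels.
#' @param teacher_name Label provenance string.
#' @return List of [labeled_sample()] objects; geometries for which the
#'   teacher fails are skipped with a warning.
#' @export
label_with_teacher <- function(geoms, teacher, forces = TRUE,
                               teacher_name = "teacher") {
  out <- list()
  for (g in geoms) {
    res <- tryCatch(calc_eval(teacher, g, forces = forces),
                    error = function(e) NULL)
    if (is.null(res) || !is.finite(res$energy)) {
      warning("teacher failed on a geometry; sample skipped")
      next
    }
    out[[length(out) + 1]] <- labeled_sample(g, res$energy, res$forces,
                                             teacher = teacher_name)
  }
  out
}

#' Train a descriptor-regression surrogate
#'
#' Ridge regression of teacher energies (per-atom weighted) and, when the
#' samples carry them and `force_weight > 0`, forces, on pooled per-element
#' descriptor sums. Deterministic given `(samples, seed)`; the seed only
#' matters through optional subsampling by the caller.
#'
#' @param samples List of [labeled_sample()].
#' @param basis A [descriptor_basis()]; defaults to one spanning the sample
#'   elements.
#' @param regularization Ridge penalty (default 1e-8).
#' @param force_weight Relative weight of force residuals (default 0.1;
#'   0 disables force fitting).
#' @param seed Integer recorded in the model metadata.
#' @return A `csp_surrogate` model.
#' @export
train_surrogate <- function(samples, basis = NULL, regularization = 1e-8,
                            force_weight = 0.1, seed = 0L) {
  if (length(samples) == 0) stop("empty sample set")
  els <- sort(unique(unlist(lapply(samples, function(s) as_atoms(s$geometry)$symbols))))
  if (is.null(basis)) basis <- descriptor_basis(els)
  ne <- length(basis$elements)
  nf <- ne * basis$n_basis
  ncol_w <- ne * (nf + 1)
  rows <- list(); ys <- list()
  for (s in samples) {
    at <- as_atoms(s$geometry)
    X <- descriptors(s$geometry, basis)
    eidx <- match(at$symbols, basis$elements)
    row <- numeric(ncol_w)
    for (i in seq_along(eidx)) {
      off <- (eidx[i] - 1) * (nf + 1)
      row[off + seq_len(nf)] <- row[off + seq_len(nf)] + X[i, ]
      row[off + nf + 1] <- row[off + nf + 1] + 1        # per-element bias
    }
    w_e <- 1 / s$n_atoms                                 # energy-per-atom loss
    rows[[length(rows) + 1]] <- row * w_e
    ys[[length(ys) + 1]] <- s$energy * w_e
    if (force_weight > 0 && !is.null(s$forces)) {
      J <- descriptor_force_design(s$geometry, basis)
      rows[[length(rows) + 1]] <- -J * force_weight
      ys[[length(ys) + 1]] <- as.numeric(t(s$forces)) * force_weight
    }
  }
  A <- do.call(rbind, rows)
  y <- unlist(ys)
  AtA <- crossprod(A) + diag(regularization, ncol_w)
  w <- solve(AtA, crossprod(A, y))
  structure(list(basis = basis, weights = as.numeric(w),
                 meta = list(seed = seed, n_samples = length(samples),
                             regularization = regularization,
                             force_weight = force_weight)),
            class = "csp_surrogate")
}

#' Predict with a surrogate model
#' @param model A `csp_surrogate`.
#' @param geom Geometry.
#' @param forces Also return analytic forces.
#' @return List with `energy` and optionally `forces`.
#' @export
surrogate_predict <- function(model, geom, forces = FALSE) {
  basis <- model$basis
  at <- as_atoms(geom)
  X <- descriptors(geom, basis)
  ne <- length(basis$elements)
  nf <- ne * basis$n_basis
  eidx <- match(at$symbols, basis$elements)
  if (anyNA(eidx)) stop("geometry contains elements outside the model basis")
  E <- 0
  for (i in seq_along(eidx)) {
    off <- (eidx[i] - 1) * (nf + 1)
    E <- E + sum(model$weights[off + seq_len(nf)] * X[i, ]) +
      model$weights[off + nf + 1]
  }
  out <- list(energy = E)
  if (forces) {
    J <- descriptor_force_design(geom, basis)
    f <- -as.numeric(J %*% model$weights)
    out$forces <- matrix(f, ncol = 3, byrow = TRUE)
  }
  out
}

#' Surrogate model as a Calculator
#' @param model A `csp_surrogate` (or list of them: the ensemble mean is used).
#' @export
surrogate_calculator <- function(model) {
  models <- if (inherits(model, "csp_surrogate")) list(model) else model
  structure(list(models = models),
            class = c("csp_calc_surrogate", "csp_calculator"),
            capabilities = c(energy = TRUE, forces = TRUE, stress = FALSE,
                             analytic_hessian = FALSE, charges = FALSE))
}

#' @rdname calc_eval
#' @export
calc_eval.csp_calc_surrogate <- function(calc, geom, forces = FALSE, stress = FALSE) {
  preds <- lapply(calc$models, surrogate_predict, geom = geom, forces = forces)
  out <- list(energy = mean(vapply(preds, function(p) p$energy, 0)))
  if (forces) out$forces <- Reduce(`+`, lapply(preds, function(p) p$forces)) /
      length(preds)
  if (stress) out$stress <- numerical_stress(calc, geom)
  out
}

#' Train an ensemble of surrogate models on random subsets
#'
#' Each member is trained on an independent random draw of `subset_frac` of
#' the samples (distinct sub-seeds derived from `seed`), providing the
#' diversity that powers ensemble-uncertainty estimates.
#'
#' @param samples Labeled samples.
#' @param n_models Ensemble size (default 4).
#' @param subset_frac Fraction of samples per member (default 0.8).
#' @param seed Integer seed.
#' @inheritParams train_surrogate
#' @return List of `csp_surrogate` models.
#' @export
train_ensemble <- function(samples, n_models = 4, subset_frac = 0.8,
                           basis = NULL, regularization = 1e-8,
                           force_weight = 0.1, seed = 1L) {
  if (is.null(basis)) {
    els <- sort(unique(unlist(lapply(samples,
                                     function(s) as_atoms(s$geometry)$symbols))))
    basis <- descriptor_basis(els)
  }
  lapply(seq_len(n_models), function(m) {
    sub_seed <- (seed * 1000L + m) %% .Machine$integer.max
    old <- .Random.seed_get()
    set.seed(sub_seed)
    idx <- sample(seq_along(samples),
                  size = max(1, round(subset_frac * length(samples))))
    .Random.seed_set(old)
    train_surrogate(samples[idx], basis = basis,
                    regularization = regularization,
                    force_weight = force_weight, seed = sub_seed)
  })
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_set <- function(s) {
  if (!is.null(s)) assign(".Random.seed", s, envir = globalenv())
}

#' Ensemble prediction with uncertainty
#'
#' @param models List of >= 2 surrogate models sharing one descriptor basis.
#' @param geom Geometry.
#' @param forces Also return the mean forces.
#' @return List with `E_mean`, `E_std` (sample standard deviation, ddof = 1)
#'   and optionally `F_mean`.
#' @export
ensemble_predict <- function(models, geom, forces = FALSE) {
  if (length(models) < 2) stop("ensemble std undefined for a single model")
  preds <- lapply(models, surrogate_predict, geom = geom, forces = forces)
  es <- vapply(preds, function(p) p$energy, 0)
  out <- list(E_mean = mean(es), E_std = stats::sd(es))
  if (forces) out$F_mean <- Reduce(`+`, lapply(preds, function(p) p$forces)) /
      length(preds)
  out
}
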