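# Ensemble-uncertainty active learning over n-mer orders: predict with the
# current 4-model ensemble, select sigma > 2 * median(sigma), label with the
# teacher, retrain, advance to the next order.

#' Ensemble uncertainty of an n-mer
#'
#' `sigma = sd(model energies) / sqrt(N)` with N the atom count and the
#' sample standard deviation (ddof = 1) over the ensemble.
#'
#' @param ensemble List of >= 2 trained surrogate models.
#' @param geom A geometry.
#' @param id Optional identifier carried through.
#' @return data.frame row: `nmer_id`, `E_std` (eV), `N`, `sigma` (eV).
#' @export
uncertainty <- function(ensemble, geom, id = NA_integer_) {
  if (length(ensemble) < 2) stop("uncertainty needs a trained ensemble (>= 2 models)")
  p <- ensemble_predict(ensemble, geom)
  N <- length(as_atoms(geom)$symbols)
  data.frame(nmer_id = id, E_std = p$E_std, N = N, sigma = p$E_std / sqrt(N))
}

#' Select high-uncertainty records
#'
#' Returns exactly the ids with `sigma > 2 * median(sigma)` (strict
#' inequality, median over the full record set of the current order).
#'
#' @param records data.frame with columns `nmer_id` and `sigma` (e.g. rows
#'   from [uncertainty()]).
#' @return Vector of selected `nmer_id`s (possibly empty).
#' @export
select_uncertain <- function(records) {
  if (nrow(records) == 0) stop("empty record set")
  thr <- 2 * stats::median(records$sigma)
  records$nmer_id[records$sigma > thr]
}

#' Run the per-order active-learning loop
#'
#' Starting from an ensemble trained on the monomer seed set, for each order
#' n in increasing sequence: predict uncertainties on that order's pool,
#' select `sigma > 2 * median`, label the selected geometries with the
#' teacher, append them to the training pool, and retrain all ensemble
#' members on fresh random subsets. Deterministic per seed.
#'
#' @param teacher A calculator used as labeling oracle.
#' @param monomer_samples Initial labeled monomer pool (list of
#'   [labeled_sample()]).
#' @param pools_by_order Named list (names = orders, e.g. `"2"`, `"3"`) of
#'   geometry lists, processed in increasing order.
#' @param n_models Ensemble size (default 4).
#' @param subset_frac Training subset fraction per member (default 0.8).
#' @param force_weight Force-residual weight passed to the trainer.
#' @param basis Optional shared [descriptor_basis()].
#' @param seed Integer seed.
#' @return List with `dataset` (all labeled samples), `ensemble` (final
#'   models) and `history` (tibble: order, pool size, median sigma,
#'   n_selected).
#' @export
run_al <- function(teacher, monomer_samples, pools_by_order, n_models = 4,
                   subset_frac = 0.8, force_weight = 0.1, basis = NULL,
                   seed = 1L) {
  stopifnot(length(monomer_samples) >= 1)
  if (is.null(basis)) {
    els <- sort(unique(unlist(lapply(
      c(monomer_samples, unlist(pools_by_order, recursive = FALSE)),
      function(s) {
        g <- if (inherits(s, "csp_sample")) s$geometry else s
        as_atoms(g)$symbols
      }))))
    basis <- descriptor_basis(els)
  }
  pool <- monomer_samples
  ens <- train_ensemble(pool, n_models = n_models, subset_frac = subset_frac,
                        basis = basis, force_weight = force_weight, seed = seed)
  orders <- sort(as.integer(names(pools_by_order)))
  history <- list()
  for (ord in orders) {
    geoms <- pools_by_order[[as.character(ord)]]
    recs <- do.call(rbind, lapply(seq_along(geoms), function(i) {
      uncertainty(ens, geoms[[i]], id = i)
    }))
    sel <- select_uncertain(recs)
    if (length(sel) > 0) {
      labeled <- label_with_teacher(geoms[sel], teacher)
      pool <- c(pool, labeled)
      ens <- train_ensemble(pool, n_models = n_models,
                            subset_frac = subset_frac, basis = basis,
                            force_weight = force_weight,
                            seed = seed + ord)
    }
    history[[length(history) + 1]] <- data.frame(
      order = ord, pool_size = length(geoms),
      median_sigma = stats::median(recs$sigma), n_selected = length(sel))
  }
  list(dataset = pool, ensemble = ens,
       history = tibble::as_tibble(do.call(rbind, history)))
}

#' Benchmark active learning against random selection
#'
#' Builds a toy flexible-diatomic teacher (intermolecular Lennard-Jones plus
#' harmonic bonds), a perturbed-monomer seed set, dimer and trimer candidate
#' pools and a held-out evaluation set; runs the per-order AL loop, then a
#' random-selection baseline with exactly the same labeling budget per
#' order; returns both hold-out energy MAEs.
#'
#' @param seed Integer seed (controls pools, hold-out and both runs).
#' @param n_dimers,n_trimers Pool sizes (defaults 200 and 100).
#' @param n_monomers Monomer seed-set size (default 40).
#' @param n_holdout Hold-out set size (default 60).
#' @return List: `mae_al`, `mae_random`, `n_selected` (per order), `history`.
#' @export
al_vs_random_benchmark <- function(seed, n_dimers = 200, n_trimers = 100,
                                   n_monomers = 40, n_holdout = 60) {
  set.seed(seed)
  eps <- 0.02; sig <- 3.0
  lj <- pair_potential("lj", list("N-N" = c(eps = eps, sigma = sig)),
                       cutoff = 9, intermolecular_only = TRUE)
  teacher <- composite_calculator(lj, bond_calculator(k = 30, r0 = 1.10))
  jitter_mol <- function() {
    b <- 1.10 + stats::rnorm(1, sd = 0.05)
    molecule(c("N", "N"), rbind(c(0, 0, 0), c(0, 0, b)))
  }
  rand_rot <- function(p) p %*% t(random_rotation())
  # clusters with a controlled closest-contact distance: the candidate pools
  # are mostly weakly interacting (far separations) with a minority of
  # strongly interacting close-contact geometries -- the informative tail an
  # uncertainty-driven selector should find
  mk_cluster <- function(n, d_range) {
    mols <- list(jitter_mol())
    for (m in seq_len(n - 1)) {
      d_target <- stats::runif(1, d_range[1], d_range[2])
      repeat {
        u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
        mm <- jitter_mol()
        pos0 <- rand_rot(mm$positions)
        prev <- mols[[m]]
        # walk along u until the closest contact to the previous molecule
        # equals d_target
        lo <- 0; hi <- 20
        for (it in 1:40) {
          mid <- (lo + hi) / 2
          d <- min_cross_dist(sweep(pos0, 2, -mid * u), prev$positions)
          if (d < d_target) lo <- mid else hi <- mid
        }
        pos <- sweep(pos0, 2, -hi * u)
        ok <- all(vapply(mols, function(pv) {
          min_cross_dist(pos, pv$positions) > d_range[1] - 0.3
        }, TRUE))
        if (ok) { mols[[m + 1]] <- molecule(c("N", "N"), pos); break }
      }
    }
    nmer(mols)
  }
  draw_range <- function() {
    if (stats::runif(1) < 0.8) c(4.5, 8) else c(3.0, 3.8)
  }
  label <- function(g) {
    r <- calc_eval(teacher, g, forces = TRUE)
    labeled_sample(g, r$energy, r$forces, teacher = "lj+bond")
  }
  monomers <- lapply(seq_len(n_monomers), function(i) label(jitter_mol()))
  dimers <- lapply(seq_len(n_dimers), function(i) mk_cluster(2, draw_range()))
  trimers <- lapply(seq_len(n_trimers), function(i) mk_cluster(3, draw_range()))
  holdout <- lapply(seq_len(n_holdout), function(i) {
    label(mk_cluster(if (i %% 2 == 0) 2 else 3, c(3.0, 6)))
  })
  basis <- descriptor_basis("N", cutoff = 5)
  pools <- list("2" = dimers, "3" = trimers)
  al <- run_al(teacher, monomers, pools, basis = basis, seed = seed)
  mae_of <- function(ens) {
    errs <- vapply(holdout, function(s) {
      abs(ensemble_predict(ens, s$geometry)$E_mean - s$energy)
    }, 0)
    mean(errs)
  }
  n_sel <- al$history$n_selected
  set.seed(seed + 500)
  pool_rand <- monomers
  for (k in seq_along(pools)) {
    geoms <- pools[[k]]
    take <- sample(seq_along(geoms), min(n_sel[k], length(geoms)))
    pool_rand <- c(pool_rand, lapply(geoms[take], label))
  }
  ens_rand <- train_ensemble(pool_rand, basis = basis, seed = seed)
  list(mae_al = mae_of(al$ensemble), mae_random = mae_of(ens_rand),
       n_selected = n_sel, history = al$history)
}

#' Label an entire pool without active learning
#'
#' The no-selection baseline: every geometry in every pool is labeled with
#' the teacher and a single ensemble is trained on the union.
#'
#' @inheritParams run_al
#' @export
run_no_al <- function(teacher, monomer_samples, pools_by_order, n_models = 4,
                      subset_frac = 0.8, force_weight = 0.1, basis = NULL,
                      seed = 1L) {
  pool <- c(monomer_samples,
            label_with_teacher(unlist(pools_by_order, recursive = FALSE),
                               teacher))
  ens <- train_ensemble(pool, n_models = n_models, subset_frac = subset_frac,
                        basis = basis, force_weight = force_weight, seed = seed)
  list(dataset = pool, ensemble = ens)
}
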