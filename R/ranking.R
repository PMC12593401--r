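# Polymorph ranking: energy-density landscapes, agreement metrics against a
# reference ranking (MAE/RMSE/Kendall tau-b/matched fraction), and molecular
# cluster RMSD between crystal structures.

#' Energy-density landscape table
#'
#' Relative lattice energies (kJ/mol per molecule above the global minimum)
#' with densities, sorted ascending, ties broken by structure id.
#'
#' @param structures List of `csp_crystal`.
#' @param energies_per_molecule Energies in eV per molecule, same length.
#' @param ids Optional structure ids (default 1..n).
#' @return Tibble: `structure_id`, `density` (g/cm^3), `E_rel` (kJ/mol),
#'   `rank`, `space_group`.
#' @export
landscape_table <- function(structures, energies_per_molecule, ids = NULL) {
  n <- length(structures)
  if (n == 0) stop("empty structure list")
  stopifnot(length(energies_per_molecule) == n)
  if (is.null(ids)) ids <- seq_len(n)
  E_rel <- (energies_per_molecule - min(energies_per_molecule)) *
    csp_constants$eV_kJmol
  tab <- tibble::tibble(
    structure_id = ids,
    density = vapply(structures, density_gcm3, 0),
    E_rel = E_rel,
    space_group = vapply(structures, function(s) s$space_group, 0L))
  o <- order(tab$E_rel, tab$structure_id)
  tab <- tab[o, ]
  tab$rank <- seq_len(n)
  tab[, c("structure_id", "density", "E_rel", "rank", "space_group")]
}

#' Kendall rank correlation (tau-b, tie-aware)
#'
#' Direct O(n^2) evaluation of concordant/discordant pairs with the tau-b
#' tie correction.
#'
#' @param x,y Paired numeric vectors.
#' @return tau-b in [-1, 1]; NA when either vector is constant.
#' @export
kendall_tau_b <- function(x, y) {
  n <- length(x)
  stopifnot(length(y) == n)
  C <- 0; D <- 0; Tx <- 0; Ty <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    dx <- sign(x[j] - x[i]); dy <- sign(y[j] - y[i])
    if (dx == 0 && dy == 0) next
    if (dx == 0) { Tx <- Tx + 1; next }
    if (dy == 0) { Ty <- Ty + 1; next }
    if (dx == dy) C <- C + 1 else D <- D + 1
  }
  den <- sqrt((C + D + Tx) * (C + D + Ty))
  if (den == 0) return(NA_real_)
  (C - D) / den
}

#' Model-vs-reference ranking metrics
#'
#' MAE and RMSE over paired relative lattice energies (kJ/mol), Kendall
#' tau-b over the induced rankings, and optionally the fraction of
#' structures whose relaxed geometry still matches its reference counterpart
#' under the duplicate-removal criterion.
#'
#' @param model_E_rel,reference_E_rel Paired relative energies, kJ/mol.
#' @param model_structures,reference_structures Optional paired structure
#'   lists for the matched fraction.
#' @param tolerances A [match_tolerances()] for the matched fraction.
#' @return Tibble: `MAE`, `RMSE`, `kendall_tau`, `matched_fraction` (%),
#'   `n`.
#' @export
ranking_metrics <- function(model_E_rel, reference_E_rel,
                            model_structures = NULL,
                            reference_structures = NULL,
                            tolerances = match_tolerances()) {
  n <- length(model_E_rel)
  stopifnot(length(reference_E_rel) == n)
  r <- model_E_rel - reference_E_rel
  tau <- if (n >= 2) kendall_tau_b(model_E_rel, reference_E_rel) else {
    warning("fewer than 2 pairs: Kendall tau undefined")
    NA_real_
  }
  matched <- NA_real_
  if (!is.null(model_structures) && !is.null(reference_structures)) {
    stopifnot(length(model_structures) == length(reference_structures))
    ok <- vapply(seq_along(model_structures), function(i) {
      structures_match(model_structures[[i]], reference_structures[[i]],
                       tolerances)
    }, TRUE)
    matched <- 100 * mean(ok)
  }
  tibble::tibble(MAE = mean(abs(r)), RMSE = sqrt(mean(r^2)),
                 kendall_tau = tau, matched_fraction = matched, n = n)
}

#' Relative reduction of an error metric
#'
#' `100 (baseline - value) / baseline`, reported to one decimal.
#'
#' @param baseline Baseline metric (> 0).
#' @param value Improved metric.
#' @return Percentage reduction (full precision; use `round(x, 1)` for
#'   report formatting).
#' @export
relative_reduction <- function(baseline, value) {
  if (baseline <= 0) stop("baseline must be > 0")
  100 * (baseline - value) / baseline
}

# Kabsch least-squares superposition: rotate B onto A (both centred)
kabsch_rmsd <- function(A, B) {
  Ac <- sweep(A, 2, colMeans(A))
  Bc <- sweep(B, 2, colMeans(B))
  s <- svd(t(Bc) %*% Ac)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  Br <- Bc %*% t(R)
  sqrt(mean(rowSums((Ac - Br)^2)))
}

#' Molecular-cluster RMSD between two crystal structures
#'
#' Builds a cluster of up to `n_molecules` whole molecules around a central
#' molecule in each structure (nearest first), matches molecules greedily by
#' centroid distance after centring, superposes the matched atoms by
#' least-squares rotation (Kabsch), and reports the larger of the two
#' directed RMSDs. Hydrogens are excluded by default.
#'
#' @param a,b `csp_crystal` objects of the same molecular composition.
#' @param n_molecules Cluster size (default 15).
#' @param include_hydrogens Keep H atoms (default FALSE).
#' @param cutoff Shell cutoff used to gather candidates, A (default 12).
#' @return RMSD in Angstrom; attribute `"flagged"` is TRUE when the shells
#'   had unequal molecule counts (the common count is used).
#' @export
cluster_rmsd <- function(a, b, n_molecules = 15, include_hydrogens = FALSE,
                         cutoff = 12) {
  clus <- function(s) {
    sh <- molecular_shell(identify_molecules(s), 1, cutoff)
    cen <- sh[[1]]
    if (length(sh) > 1) {
      dmin <- vapply(sh[-1], function(m) min_cross_dist(m$positions,
                                                        cen$positions), 0)
      sh <- c(sh[1], sh[-1][order(dmin)])
    }
    sh[seq_len(min(n_molecules, length(sh)))]
  }
  ca <- clus(a); cb <- clus(b)
  flagged <- length(ca) != length(cb)
  nmol <- min(length(ca), length(cb))
  ca <- ca[seq_len(nmol)]; cb <- cb[seq_len(nmol)]
  directed <- function(X, Y) {
    # centre both clusters, match molecules greedily by centroid distance
    allX <- do.call(rbind, lapply(X, function(m) m$positions))
    allY <- do.call(rbind, lapply(Y, function(m) m$positions))
    cX <- colMeans(allX); cY <- colMeans(allY)
    cenX <- t(vapply(X, function(m) colMeans(m$positions) - cX, numeric(3)))
    cenY <- t(vapply(Y, function(m) colMeans(m$positions) - cY, numeric(3)))
    used <- logical(nmol)
    pairs <- integer(nmol)
    for (i in seq_len(nmol)) {
      d <- rowSums((cenY - matrix(cenX[i, ], nmol, 3, byrow = TRUE))^2)
      d[used] <- Inf
      j <- which.min(d)
      used[j] <- TRUE
      pairs[i] <- j
    }
    A <- NULL; B <- NULL
    for (i in seq_len(nmol)) {
      mx <- X[[i]]; my <- Y[[pairs[i]]]
      keep <- if (include_hydrogens) seq_along(mx$symbols)
              else which(mx$symbols != "H")
      if (!identical(mx$symbols[keep], my$symbols[keep])) {
        stop("cluster molecules have different composition")
      }
      A <- rbind(A, mx$positions[keep, , drop = FALSE])
      B <- rbind(B, my$positions[keep, , drop = FALSE])
    }
    kabsch_rmsd(A, B)
  }
  out <- max(directed(ca, cb), directed(cb, ca))
  attr(out, "flagged") <- flagged
  out
}

#' Energy-density landscape plot
#' @param object A tibble from [landscape_table()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_landscape <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = density, y = E_rel)) +
    ggplot2::geom_point(ggplot2::aes(colour = factor(space_group))) +
    ggplot2::labs(x = expression(density ~ (g ~ cm^-3)),
                  y = expression(Delta * E ~ (kJ ~ mol^-1)),
                  colour = "space group") +
    ggplot2::theme_minimal()
}
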