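# Seeded synthetic fixtures with known reference values, synthetic E(V)
# curves, and the end-to-end pipeline driver.

#' Build a toy fixture crystal
#'
#' Kinds (each ships its reference metadata in attributes):
#' \describe{
#'   \item{lj_fcc}{4-atom conventional fcc Ar cell; `a0` chosen at the
#'     Lennard-Jones nearest-neighbour optimum for the supplied parameters.}
#'   \item{rigid_diatomic_crystal}{one N2-like rigid diatomic per cell in a
#'     roomy orthorhombic box.}
#'   \item{einstein_crystal}{simple-cubic Ar sites; metadata carries the site
#'     spring `k` and `omega0 = sqrt(k/m)`.}
#'   \item{rocksalt_ions}{Na+/Cl- rocksalt with +-1 e charges; metadata
#'     carries the nearest-neighbour distance.}
#'   \item{one_d_chain}{atoms spaced `a` along x in a wide box; with a
#'     harmonic spring calculator the longitudinal dispersion is
#'     `2 sqrt(k/m) |sin(q a / 2)|`.}
#' }
#'
#' @param kind Fixture kind.
#' @param noise Gaussian site noise, A (default 0 = ideal geometry).
#' @param seed Integer seed.
#' @param a Lattice constant / spacing override, A.
#' @param k Spring constant for einstein/chain metadata, eV/A^2.
#' @param eps,sigma LJ parameters used for the lj_fcc geometry.
#' @return A `csp_crystal` with reference metadata attributes.
#' @export
make_fixture <- function(kind = c("lj_fcc", "rigid_diatomic_crystal",
                                  "einstein_crystal", "rocksalt_ions",
                                  "one_d_chain"),
                         noise = 0, seed = 1L, a = NULL, k = 1,
                         eps = 0.0104, sigma = 3.4) {
  kind <- match.arg(kind)
  set.seed(seed)
  out <- switch(kind,
    lj_fcc = {
      # fcc nearest neighbour d = a/sqrt(2); LJ pair optimum 2^(1/6) sigma
      if (is.null(a)) a <- 2^(1 / 6) * sigma * sqrt(2)
      fr <- rbind(c(0, 0, 0), c(.5, .5, 0), c(.5, 0, .5), c(0, .5, .5))
      s <- crystal_structure(diag(3) * a, rep("Ar", 4), fr, Z = 4)
      attr(s, "reference") <- list(a0 = a, eps = eps, sigma = sigma)
      s
    },
    rigid_diatomic_crystal = {
      if (is.null(a)) a <- 6
      bond <- 1.10
      fr <- rbind(c(.5, .5, .5 - bond / (2 * a)), c(.5, .5, .5 + bond / (2 * a)))
      s <- crystal_structure(diag(3) * a, c("N", "N"), fr, Z = 1)
      attr(s, "reference") <- list(bond = bond)
      s
    },
    einstein_crystal = {
      if (is.null(a)) a <- 5
      s <- crystal_structure(diag(3) * a, "Ar", rbind(c(0, 0, 0)), Z = 1)
      m <- element_spec("Ar")$mass
      attr(s, "reference") <- list(k = k, omega0 = sqrt(k / m) *
                                     csp_constants$freq_factor)
      s
    },
    rocksalt_ions = {
      if (is.null(a)) a <- 5.64
      fr <- rbind(c(0, 0, 0), c(.5, .5, 0), c(.5, 0, .5), c(0, .5, .5),
                  c(.5, 0, 0), c(0, .5, 0), c(0, 0, .5), c(.5, .5, .5))
      s <- crystal_structure(diag(3) * a, c(rep("Na", 4), rep("Cl", 4)), fr,
                             Z = 4, charges = c(rep(1, 4), rep(-1, 4)))
      attr(s, "reference") <- list(d_nn = a / 2, madelung = 1.747564594633)
      s
    },
    one_d_chain = {
      if (is.null(a)) a <- 2.5
      L <- 20
      s <- crystal_structure(rbind(c(a, 0, 0), c(0, L, 0), c(0, 0, L)),
                             "Ar", rbind(c(0, 0, 0)), Z = 1)
      m <- element_spec("Ar")$mass
      attr(s, "reference") <- list(a = a, k = k,
                                   omega_max = 2 * sqrt(k / m) *
                                     csp_constants$freq_factor)
      s
    })
  if (noise > 0) {
    cellmat <- as.matrix(out$lattice)
    disp <- matrix(stats::rnorm(3 * length(out$species), sd = noise), ncol = 3)
    out$frac_coords <- (out$frac_coords + disp %*% solve(cellmat)) %% 1
  }
  out
}

#' Reference calculators for the fixtures
#'
#' @param kind Fixture kind.
#' @param k Spring constant (einstein / chain / diatomic), eV/A^2.
#' @param r0 Spring rest length, A.
#' @param eps,sigma,cutoff LJ parameters.
#' @param fixture A fixture crystal (needed for `einstein_crystal` tethers).
#' @return A calculator matched to [make_fixture()] geometries.
#' @export
fixture_calculator <- function(kind, k = 1, r0 = 2.5, eps = 0.0104,
                               sigma = 3.4, cutoff = 2.5 * sigma,
                               fixture = NULL) {
  switch(kind,
    lj_fcc = pair_potential("lj", list("Ar-Ar" = c(eps = eps, sigma = sigma)),
                            cutoff = cutoff),
    einstein_crystal = {
      stopifnot(!is.null(fixture))
      einstein_calculator(fixture, k)
    },
    one_d_chain = pair_potential("harmonic",
                                 list("Ar-Ar" = c(k = k, r0 = r0)),
                                 cutoff = 1.5 * r0, shift = FALSE),
    rocksalt_ions = ewald_calculator(),
    stop("no reference calculator for kind ", kind))
}

#' Synthetic Birch-Murnaghan E(V) data
#'
#' @param params Named list/vector with F0 (eV), V0 (A^3), B0 (eV/A^3), B0p.
#' @param n_points Number of volumes (default 17, spanning 0.95-1.15 V0).
#' @param noise Gaussian noise sd, eV (default 0).
#' @param seed Integer seed.
#' @return Tibble with columns `V`, `F`.
#' @export
make_eos_data <- function(params, n_points = 17, noise = 0, seed = 1L) {
  p <- as.list(params)
  V <- seq(0.95, 1.15, length.out = n_points) * p$V0
  F_ <- birch_murnaghan(V, p$F0, p$V0, p$B0, p$B0p)
  if (noise > 0) {
    set.seed(seed)
    F_ <- F_ + stats::rnorm(n_points, sd = noise)
  }
  tibble::tibble(V = V, F = F_)
}

#' Run the end-to-end CSP pipeline on toy inputs
#'
#' Executes the requested stages in order (`generate`, `relax`, `rank`, and
#' optionally `qha` on the best structure), persisting intermediates under
#' `out_dir` and returning a manifest. All randomness flows from `seed`.
#'
#' @param molecule A `csp_molecule` to pack (default: rigid N2).
#' @param calculator Energy model (default: an N2 LJ toy).
#' @param n_structures Number of generation candidates (default 10).
#' @param stages Ordered subset of `c("generate", "relax", "rank", "qha")`.
#' @param space_group Space group for generation (default "P1").
#' @param Z Molecules per cell (default 1).
#' @param s_r Contact criterion (default 0.8).
#' @param seed Global seed.
#' @param out_dir Output directory (`NULL` = nothing persisted).
#' @return Manifest list: per-stage counts, timings, and result tables.
#' @export
run_pipeline <- function(molecule = NULL, calculator = NULL,
                         n_structures = 10,
                         stages = c("generate", "relax", "rank"),
                         space_group = "P1", Z = 1, s_r = 0.8, seed = 1L,
                         out_dir = NULL) {
  stopifnot(all(stages %in% c("generate", "relax", "rank", "qha")))
  if (is.null(molecule)) {
    molecule <- molecule_n2()
  }
  if (is.null(calculator)) {
    calculator <- composite_calculator(
      pair_potential("lj", list("N-N" = c(eps = 0.01, sigma = 3.2)),
                     cutoff = 8, intermolecular_only = TRUE),
      bond_calculator(k = 30, r0 = 1.10))
  }
  manifest <- list(seed = seed, stages = list())
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE,
                                    recursive = TRUE)
  crit <- contact_criterion(s_r)
  structures <- list(); energies <- numeric(0)
  for (stage in stages) {
    t0 <- proc.time()[["elapsed"]]
    if (stage == "generate") {
      structures <- list()
      attempts <- integer(0)
      for (i in seq_len(n_structures)) {
        st <- tryCatch(
          generate_candidate(molecule, space_group, Z, crit,
                             generation_config(max_attempts = 100),
                             seed = seed * 1000L + i),
          csp_generation_failure = function(e) NULL)
        if (!is.null(st)) {
          structures[[length(structures) + 1]] <- st
          attempts <- c(attempts, attr(st, "attempts"))
        }
      }
      if (!is.null(out_dir)) {
        for (i in seq_along(structures)) {
          write_cif(structures[[i]],
                    file.path(out_dir, sprintf("gen_%03d.cif", i)))
        }
      }
      manifest$stages$generate <- list(requested = n_structures,
                                       generated = length(structures),
                                       attempts = attempts)
    } else if (stage == "relax") {
      relaxed <- list(); energies <- numeric(0)
      for (i in seq_along(structures)) {
        r <- tryCatch(relax(structures[[i]], calculator,
                            relax_settings(max_steps = 200)),
                      error = function(e) NULL)
        if (!is.null(r)) {
          rs <- r$structure
          rs$molecule_of_site <- structures[[i]]$molecule_of_site
          relaxed[[length(relaxed) + 1]] <- rs
          energies <- c(energies, r$energy)
        }
      }
      structures <- relaxed
      manifest$stages$relax <- list(relaxed = length(structures),
                                    energies = energies)
    } else if (stage == "rank") {
      dd <- deduplicate(structures, energies = energies)
      uniq <- dd$unique
      uenergies <- energies[dd$representative]
      tab <- landscape_table(uniq, uenergies / vapply(uniq, function(s) s$Z, 0L))
      if (!is.null(out_dir)) {
        utils::write.csv(tab, file.path(out_dir, "landscape.csv"),
                         row.names = FALSE)
      }
      manifest$stages$rank <- list(n_unique = length(uniq),
                                   clusters = dd$cluster, landscape = tab)
    } else if (stage == "qha") {
      best <- which.min(energies)
      tc <- qha(structures[[best]], calculator, T_list = c(0, 300),
                mesh = c(3, 3, 3), min_supercell_length = 6)
      manifest$stages$qha <- list(summary = tc$summary)
    }
    manifest$stages[[stage]]$elapsed <-
      proc.time()[["elapsed"]] - t0
  }
  if (!is.null(out_dir)) {
    saveable <- manifest
    saveable$stages <- lapply(saveable$stages, function(s) {
      s$landscape <- NULL; s
    })
    jsonlite::write_json(saveable, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  manifest
}

#' Rigid N2-like test molecule
#' @param bond Bond length, A (default 1.10).
#' @export
molecule_n2 <- function(bond = 1.10) {
  molecule(c("N", "N"), rbind(c(0, 0, 0), c(0, 0, bond)))
}
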