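test_that("volume estimate follows the vdW-sphere formula", {
  m <- molecule("Ar", rbind(c(0, 0, 0)))
  v1 <- estimate_volume(m, 1, packing_factor = 1, vdw_radii = 2)
  expect_equal(v1, 4 / 3 * pi * 8, tolerance = 1e-9)
  expect_equal(estimate_volume(m, 4, packing_factor = 1, vdw_radii = 2),
               4 * v1, tolerance = 1e-9)
  expect_equal(estimate_volume(m, 1, packing_factor = 0.55, vdw_radii = 2),
               v1 / 0.55, tolerance = 1e-9)
})

test_that("contact violations apply the s_r threshold on vdW radii", {
  # two Ar atoms (r_vdw 1.88) as separate molecules in a huge cell
  mk <- function(d) {
    s <- crystal_structure(diag(3) * 30, c("Ar", "Ar"),
                           rbind(c(.5, .5, .5), c(.5, .5, .5 + d / 30)),
                           molecule_of_site = c(1, 2))
    attr(s, "ufrac") <- s$frac_coords
    s
  }
  rv <- element_spec("Ar")$r_vdw
  thr <- 0.8 * 2 * rv         # 3.008 A
  v1 <- contact_violations(mk(thr - 0.5), contact_criterion(0.8))
  expect_equal(nrow(v1), 1)
  expect_equal(v1$threshold, thr, tolerance = 1e-9)
  expect_equal(nrow(contact_violations(mk(thr + 0.5), contact_criterion(0.8))), 0)
  # single molecule alone: no intermolecular pairs
  solo <- crystal_structure(diag(3) * 30, c("N", "N"),
                            rbind(c(.5, .5, .5), c(.5, .5, .5 + 1.1 / 30)),
                            molecule_of_site = c(1, 1))
  attr(solo, "ufrac") <- solo$frac_coords
  expect_equal(nrow(contact_violations(solo, contact_criterion(0.8))), 0)
})

test_that("contact violations match brute-force image enumeration", {
  set.seed(23)
  for (rep in 1:100) {
    n <- sample(2:4, 1)
    cell <- diag(stats::runif(3, 4, 8)) + matrix(stats::rnorm(9, sd = 0.5), 3)
    if (det(cell) <= 20) next
    s <- crystal_structure(cell, sample(c("Ar", "Ne", "He"), n, replace = TRUE),
                           matrix(stats::runif(3 * n), n, 3),
                           molecule_of_site = seq_len(n))
    attr(s, "ufrac") <- s$frac_coords
    sr <- stats::runif(1, 0.7, 0.9)
    expect_equal(nrow(contact_violations(s, contact_criterion(sr))),
                 brute_contacts(s, sr))
  }
})

test_that("generated candidates obey symmetry and contact constraints", {
  m <- molecule_n2()
  c1 <- generate_candidate(m, "P1", 1, contact_criterion(0.8),
                           generation_config(max_attempts = 200), seed = 5)
  expect_equal(max(c1$molecule_of_site), 1)
  expect_equal(nrow(contact_violations(c1, contact_criterion(0.8))), 0)

  c2 <- generate_candidate(m, "P-1", 2, contact_criterion(0.8),
                           generation_config(max_attempts = 300), seed = 7)
  expect_equal(max(c2$molecule_of_site), 2)
  expect_equal(nrow(contact_violations(c2, contact_criterion(0.8))), 0)
  # the inversion operator maps the structure onto itself within 1e-6
  perm <- cspkit:::op_maps_structure(c2, -diag(3), c(0, 0, 0), 1e-6)
  expect_false(is.null(perm))

  c3 <- generate_candidate(m, "P21/c", 4, contact_criterion(0.75),
                           generation_config(max_attempts = 500), seed = 11)
  expect_equal(max(c3$molecule_of_site), 4)
  for (op in space_group_ops("P21/c")) {
    expect_false(is.null(cspkit:::op_maps_structure(c3, op$W, op$w, 1e-6)))
  }

  # generation is bit-reproducible per seed
  c1b <- generate_candidate(m, "P1", 1, contact_criterion(0.8),
                            generation_config(max_attempts = 200), seed = 5)
  expect_identical(c1$frac_coords, c1b$frac_coords)
  expect_identical(as.matrix(c1$lattice), as.matrix(c1b$lattice))

  # Z not a multiple of the multiplicity
  expect_error(generate_candidate(m, "P-1", 3), "multiplicity")
  # infeasible volume
  expect_error(
    generate_candidate(m, "P1", 1, contact_criterion(0.8),
                       generation_config(volume_scale = 0.1,
                                         max_attempts = 8), seed = 1),
    class = "csp_generation_failure")
})

test_that("rigid press compresses without breaking rigidity or contacts", {
  m <- molecule_n2()
  crit <- contact_criterion(0.8)
  c2 <- generate_candidate(m, "P-1", 2, crit, generation_config(), seed = 7)
  rp <- rigid_press(c2, crit, expansion_factor = 1.6, max_iter = 60)
  expect_lt(cell_volume(rp$lattice), cell_volume(c2$lattice) * 1.6^3)
  expect_equal(nrow(contact_violations(rp, crit)), 0)
  uw <- cspkit:::unwrap_molecules(rp)
  for (mol in uw$molecules) {
    expect_equal(as.numeric(dist(mol$positions)), 1.10, tolerance = 1e-8)
  }
})

test_that("rigid press is a near-fixed point on an exactly jammed crystal", {
  # one Ar per cell in simple cubic at the exact s_r contact distance:
  # no shrink is possible without a violation
  rv <- element_spec("Ar")$r_vdw
  a <- 0.8 * 2 * rv + 1e-3
  s <- crystal_structure(diag(3) * a, "Ar", rbind(c(0, 0, 0)),
                         molecule_of_site = 1L)
  rp <- rigid_press(s, contact_criterion(0.8), expansion_factor = 1.0,
                    max_iter = 40)
  expect_lt(abs(cell_volume(rp$lattice) / cell_volume(s$lattice) - 1), 0.01)
  expect_equal(nrow(contact_violations(rp, contact_criterion(0.8))), 0)
})

test_that("single molecule compresses toward the contact shell of its images", {
  m <- molecule_n2()
  crit <- contact_criterion(0.8)
  c1 <- generate_candidate(m, "P1", 1, crit,
                           generation_config(max_attempts = 200), seed = 5)
  rp <- rigid_press(c1, crit, expansion_factor = 1.5, max_iter = 60)
  expect_equal(nrow(contact_violations(rp, crit)), 0)
  expect_lt(cell_volume(rp$lattice), cell_volume(c1$lattice))
})
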