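test_that("Lennard-Jones dimer hits its analytic minimum and zero", {
  lj <- ar_lj(cutoff = 12, shift = FALSE)
  m <- molecule(c("Ar", "Ar"), rbind(c(0, 0, 0), c(2^(1 / 6) * 3.4, 0, 0)))
  r <- calc_eval(lj, m, forces = TRUE)
  expect_equal(r$energy, -0.0104, tolerance = 1e-12)
  expect_lt(max(abs(r$forces)), 1e-8)
  m0 <- molecule(c("Ar", "Ar"), rbind(c(0, 0, 0), c(3.4, 0, 0)))
  expect_equal(calc_eval(lj, m0)$energy, 0, tolerance = 1e-14)
  expect_error(calc_eval(lj, molecule(c("N", "N"),
                                      rbind(c(0, 0, 0), c(3, 0, 0)))),
               "N-N")
})

test_that("calculators satisfy the conformance contract", {
  lj <- ar_lj()
  # forces vs central differences on a random cluster
  set.seed(2)
  mc <- molecule(rep("Ar", 10), matrix(stats::rnorm(30, sd = 3), 10, 3))
  fa <- calc_eval(lj, mc, forces = TRUE)$forces
  fn <- cspkit:::numerical_forces(lj, mc)
  expect_lt(max(abs(fa - fn)), 1e-6)
  # translation invariance
  mc2 <- cspkit:::geom_set_positions(mc, cspkit:::geom_positions(mc) + 7.3)
  expect_equal(calc_eval(lj, mc2)$energy, calc_eval(lj, mc)$energy,
               tolerance = 1e-12)
  # stress vs central strain differences on the fcc crystal
  fcc <- make_fixture("lj_fcc")
  sa <- calc_eval(lj, fcc, stress = TRUE)$stress
  sn <- cspkit:::numerical_stress(lj, fcc)
  expect_lt(max(abs(sa - sn)), 1e-7)
  # extensivity: 2x1x1 supercell has exactly twice the energy
  e1 <- calc_eval(lj, fcc)$energy
  e2 <- calc_eval(lj, make_supercell(fcc, c(2, 1, 1)))$energy
  expect_equal(e2, 2 * e1, tolerance = 1e-10)
  rs <- make_fixture("rocksalt_ions")
  er1 <- ewald_energy(rs)$energy
  er2 <- ewald_energy(make_supercell(rs, c(2, 1, 1)))$energy
  expect_equal(er2, 2 * er1, tolerance = 1e-8)
})

test_that("Ewald reproduces the rocksalt Madelung energy", {
  rs <- make_fixture("rocksalt_ions")
  ref <- attr(rs, "reference")
  E <- ewald_energy(rs)$energy
  # direct-sum reference: Madelung constant per ion pair, 4 pairs per cell
  E_ref <- -ref$madelung * csp_constants$coulomb / ref$d_nn * 4
  expect_equal(E, E_ref, tolerance = 1e-4 * abs(E_ref))
  # CsCl structure against its Madelung constant 1.762675
  a <- 4.11
  cs <- crystal_structure(diag(3) * a, c("Cs", "Cl"),
                          rbind(c(0, 0, 0), c(.5, .5, .5)), Z = 1,
                          charges = c(1, -1))
  d <- a * sqrt(3) / 2
  expect_equal(ewald_energy(cs)$energy,
               -1.762675 * csp_constants$coulomb / d,
               tolerance = 1e-4 * csp_constants$coulomb / d)
})

test_that("Ewald is splitting-parameter independent, neutral-only, zero for no charges", {
  rs <- make_fixture("rocksalt_ions")
  E1 <- ewald_energy(rs, settings = ewald_settings(alpha = 0.2))$energy
  E2 <- ewald_energy(rs, settings = ewald_settings(alpha = 0.4))$energy
  expect_lt(abs(E1 - E2) / abs(E1), 1e-7)
  z <- rs; z$charges <- rep(0, 8)
  expect_identical(ewald_energy(z)$energy, 0)
  bad <- rs; bad$charges[1] <- 2
  expect_error(ewald_energy(bad), "net charge")
  # analytic forces agree with central differences
  rs2 <- rs
  rs2$frac_coords[1, ] <- rs2$frac_coords[1, ] + c(0.03, -0.02, 0.01)
  fa <- ewald_energy(rs2, forces = TRUE)$forces
  fn <- cspkit:::numerical_forces(ewald_calculator(), rs2)
  expect_lt(max(abs(fa - fn)), 1e-6)
})

test_that("dispersion terms evaluate their closed forms", {
  r <- 3
  pair <- molecule(rep("Ar", 2), rbind(c(0, 0, 0), c(r, 0, 0)))
  expect_equal(dispersion_two_body(pair, list(C6 = list("Ar-Ar" = 10), r0 = 2)),
               -10 / (r^6 + 2^6), tolerance = 1e-12)
  expect_identical(dispersion_two_body(pair, list(C6 = list("Ar-Ar" = 0), r0 = 2)), 0)
  tri <- molecule(rep("Ar", 3),
                  rbind(c(0, 0, 0), c(r, 0, 0), c(r / 2, r * sqrt(3) / 2, 0)))
  # equilateral ATM angular factor: 3 (1/2)^3 + 1 = 1.375
  expect_equal(atm_three_body(tri, list(C9 = 2)), 1.375 * 2 / r^9,
               tolerance = 1e-12)
  expect_identical(atm_three_body(pair, list(C9 = 1)), 0)
  expect_error(atm_three_body(tri, list(C9 = -1)), "C9")
})

test_that("composite calculators add energies and forces", {
  m <- molecule_n2()
  teach <- n2_teacher()
  r <- calc_eval(teach, m, forces = TRUE)
  expect_equal(r$energy, 0, tolerance = 1e-12)  # at rest length, no LJ pair
  fn <- cspkit:::numerical_forces(teach, m)
  expect_lt(max(abs(r$forces - fn)), 1e-6)
})

test_that("einstein calculator is harmonic about its reference", {
  ein <- make_fixture("einstein_crystal", k = 2)
  calc <- einstein_calculator(ein, 2)
  g <- ein
  g$frac_coords[1, ] <- g$frac_coords[1, ] + c(0.02, 0, 0)
  d <- 0.02 * 5
  r <- calc_eval(calc, g, forces = TRUE)
  expect_equal(r$energy, 0.5 * 2 * d^2, tolerance = 1e-10)
  expect_equal(r$forces[1, 1], -2 * d, tolerance = 1e-10)
})
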