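# relaxation, symmetrization and duplicate removal

test_that("perturbed LJ-fcc relaxes back to the clean minimum", {
  lj <- ar_lj()
  r0 <- relax(make_fixture("lj_fcc"), lj, relax_settings())
  expect_true(r0$converged)
  r1 <- relax(make_fixture("lj_fcc", noise = 0.05, seed = 3), lj,
              relax_settings())
  expect_true(r1$converged)
  expect_lte(r1$rms_force, 0.001)
  a0 <- lattice_params(r0$structure$lattice)[1:3]
  a1 <- lattice_params(r1$structure$lattice)[1:3]
  expect_lt(max(abs(a1 - a0)), 1e-3)
  # energy never increases along the accepted trajectory
  expect_true(all(diff(r1$trajectory$energy) <= 1e-12))
  # already-converged input: no further steps, geometry unchanged
  r2 <- relax(r0$structure, lj, relax_settings())
  expect_lte(r2$n_steps, 1)
  expect_lt(max(abs(r2$structure$frac_coords - r0$structure$frac_coords)),
            1e-8)
})

test_that("fixed-volume mode preserves the determinant while relaxing shape", {
  lj <- ar_lj()
  r0 <- relax(make_fixture("lj_fcc"), lj, relax_settings())
  g <- r0$structure
  g$lattice <- lattice(as.matrix(g$lattice) * 1.05^(1 / 3))
  V_target <- cell_volume(g$lattice)
  r <- relax(g, lj, relax_settings(mode = "fixed_volume_variable_cell"))
  expect_lt(abs(cell_volume(r$structure$lattice) / V_target - 1), 1e-8)
  expect_gt(r$energy, r0$energy)
  expect_lte(r$rms_force, 0.001)
})

test_that("max_steps exhaustion flags a non-converged result", {
  lj <- ar_lj()
  expect_warning(
    r <- relax(make_fixture("lj_fcc", noise = 0.08, seed = 5), lj,
               relax_settings(max_steps = 1)),
    "not converged")
  expect_false(r$converged)
  expect_true(is.finite(r$rms_force))
})

test_that("symmetrize detects fcc as Fm-3m and falls back to P1", {
  fcc <- make_fixture("lj_fcc")
  sym <- symmetrize(fcc, symprec = 0.2)
  expect_equal(sym$space_group, 225)
  # broken symmetry: one site displaced by 0.5 A >> symprec
  bad <- fcc
  bad$frac_coords[1, 1] <- bad$frac_coords[1, 1] + 0.5 / 5.4
  expect_equal(symmetrize(bad, 0.2)$space_group, 1)
  # idempotence and bounded site motion
  slight <- fcc
  set.seed(8)
  slight$frac_coords <- (fcc$frac_coords +
                           matrix(stats::rnorm(12, sd = 0.1 / 5.4 / 3),
                                  4, 3)) %% 1
  s1 <- symmetrize(slight, 0.2)
  d <- (s1$structure$frac_coords - slight$frac_coords)
  d <- abs(d - round(d)) * 5.4
  expect_lt(max(d), 0.2)
  s2 <- symmetrize(s1$structure, 0.2)
  expect_equal(s2$space_group, s1$space_group)
  dd <- s2$structure$frac_coords - s1$structure$frac_coords
  expect_lt(max(abs(dd - round(dd))), 1e-8)
})

test_that("symmetrize recovers the generating space group and is idempotent", {
  m <- molecule_n2()
  for (sg in c("P-1", "P21/c")) {
    Z <- length(space_group_ops(sg))
    s <- generate_candidate(m, sg, Z, contact_criterion(0.75),
                            generation_config(max_attempts = 500),
                            seed = 13)
    sym <- symmetrize(s, 0.1)
    expect_equal(sym$name, sg)
    sym2 <- symmetrize(sym$structure, 0.1)
    expect_equal(sym2$space_group, sym$space_group)
  }
  # random P1 structures stay P1 under repeated symmetrization
  set.seed(21)
  for (rep in 1:10) {
    n <- sample(2:4, 1)
    s <- crystal_structure(random_lattice(),
                           sample(c("C", "N"), n, replace = TRUE),
                           matrix(stats::runif(3 * n), n, 3))
    s1 <- symmetrize(s, 0.2)
    s2 <- symmetrize(s1$structure, 0.2)
    expect_equal(s2$space_group, s1$space_group)
    dd <- s2$structure$frac_coords - s1$structure$frac_coords
    expect_lt(max(abs(dd - round(dd))), 1e-8)
  }
})

test_that("duplicate removal clusters translated and noisy copies", {
  m <- molecule_n2()
  A <- generate_candidate(m, "P-1", 2, contact_criterion(0.8),
                          generation_config(), seed = 7)
  At <- A
  At$frac_coords <- (A$frac_coords +
                       matrix(c(0.3, 0.1, 0.7), nrow(A$frac_coords), 3,
                              byrow = TRUE)) %% 1
  B <- generate_candidate(m, "P-1", 2, contact_criterion(0.8),
                          generation_config(), seed = 19)
  An <- A
  set.seed(4)
  An$frac_coords <- (A$frac_coords +
                       matrix(stats::rnorm(nrow(A$frac_coords) * 3,
                                           sd = 0.1 / 6), ncol = 3)) %% 1
  expect_true(structures_match(A, At))
  expect_true(structures_match(A, An))
  expect_false(structures_match(A, B))
  # 30% lattice difference is beyond ltol
  C <- A; C$lattice <- lattice(as.matrix(A$lattice) * 1.3)
  expect_false(structures_match(A, C))
  # mixed compositions never match
  D <- A; D$species <- rep("O", length(A$species))
  expect_false(structures_match(A, D))
  dd <- deduplicate(list(A, At, An, B))
  expect_equal(dd$cluster, c(1, 1, 1, 2))
  # membership is invariant to input order
  dd2 <- deduplicate(list(B, An, At, A))
  expect_equal(dd2$cluster, c(1, 2, 2, 2))
  # lowest-energy representative when energies are given
  dd3 <- deduplicate(list(A, At, An, B), energies = c(0, -1, 2, 5))
  expect_equal(dd3$representative, c(2L, 4L))
})
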