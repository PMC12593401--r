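# phonons, vibrational free energy, EOS fitting, QHA and heat capacity

cc <- csp_constants

test_that("a harmonic diatomic vibrates at sqrt(2k/m)", {
  k <- 5
  sp <- pair_potential("harmonic", list("N-N" = c(k = k, r0 = 1.1)),
                       cutoff = 1.6, shift = FALSE)
  m <- molecule(c("N", "N"), rbind(c(0, 0, 0), c(0, 0, 1.1)))
  H <- pair_hessian(sp, m)
  mass <- element_spec("N")$mass[1]
  ev <- eigen(H / mass, symmetric = TRUE, only.values = TRUE)$values
  w <- sqrt(max(ev)) * cc$freq_factor
  expect_equal(w, sqrt(2 * k / mass) * cc$freq_factor, tolerance = 1e-8)
})

test_that("supercell multiplicity is the covering ceiling", {
  s <- crystal_structure(diag(3) * 3, "Ar", rbind(c(0, 0, 0)))
  ein <- einstein_calculator(s, 1)
  fc <- hessian(s, ein, min_supercell_length = 10, asr = FALSE)
  expect_equal(attr(fc$supercell, "reps"), c(4L, 4L, 4L))
})

test_that("analytic and finite-displacement force constants agree", {
  lj <- ar_lj()
  fcc <- relax(make_fixture("lj_fcc"), lj)$structure
  fa <- hessian(fcc, lj, method = "analytic")
  fd <- hessian(fcc, lj, method = "finite_displacement")
  expect_lt(max(abs(fa$matrix - fd$matrix)), 1e-4)
  # Hessian symmetry before any symmetrization
  H <- pair_hessian(lj, make_supercell(fcc, c(2, 2, 2)))
  expect_lt(max(abs(H - t(H))), 1e-6)
})

test_that("1D chain reproduces the textbook dispersion", {
  ch <- make_fixture("one_d_chain", k = 2)
  calc <- fixture_calculator("one_d_chain", k = 2, r0 = 2.5)
  fc <- hessian(ch, calc, min_supercell_length = 10)
  mass <- element_spec("Ar")$mass
  qs <- seq(0.025, 0.5, length.out = 20)
  for (q in qs) {
    w <- phonon_frequencies(fc, c(q, 0, 0))
    ref <- 2 * sqrt(2 / mass) * abs(sin(pi * q)) * cc$freq_factor
    expect_equal(max(w) / ref, 1, tolerance = 1e-8)
  }
  # Gamma: three acoustic zeros for the sum-rule-enforced chain
  wg <- phonon_frequencies(fc, c(0, 0, 0))
  expect_lt(max(abs(wg)) / (2 * pi * 1e12), 1e-3)   # below 1e-3 THz
})

test_that("the Einstein crystal is flat at omega0 for every q", {
  ein <- make_fixture("einstein_crystal", k = 1)
  calc <- fixture_calculator("einstein_crystal", k = 1, fixture = ein)
  fc <- hessian(ein, calc, min_supercell_length = 10, asr = FALSE)
  w0 <- attr(ein, "reference")$omega0
  for (q in list(c(0, 0, 0), c(0.5, 0, 0), c(0.3, 0.1, 0.7))) {
    expect_equal(phonon_frequencies(fc, q) / w0, rep(1, 3), tolerance = 1e-10)
  }
})

test_that("f_vib matches the closed form and its limits", {
  kB <- cc$k_B
  # single-mode scalar checks via a 1-atom Einstein crystal
  ein <- make_fixture("einstein_crystal", k = 1)
  calc <- fixture_calculator("einstein_crystal", k = 1, fixture = ein)
  fc <- hessian(ein, calc, min_supercell_length = 6, asr = FALSE)
  sp <- phonon_spectrum(fc, c(2, 2, 2))
  w0 <- attr(ein, "reference")$omega0
  hw <- cc$hbar * w0
  for (T in c(0, 150, 300)) {
    ref <- 3 * (hw / 2 + if (T > 0) kB * T * log(1 - exp(-hw / (kB * T))) else 0)
    expect_equal(f_vib(sp, T), ref, tolerance = 1e-10)
  }
  expect_gte(f_vib(sp, 0), 0)                  # ZPE >= 0
  Ts <- seq(0, 400, by = 50)
  Fs <- vapply(Ts, function(T) f_vib(sp, T), 0)
  expect_true(all(diff(Fs) < 0))               # strictly decreasing in T
  # scalar formula check: hbar w = 0.01 eV at 300 K
  expect_equal(0.005 + kB * 300 * log(1 - exp(-0.01 / (kB * 300))),
               -0.024393, tolerance = 1e-4)
})

test_that("gibbs_ha composes G = E_latt + F_vib + pV", {
  ein <- make_fixture("einstein_crystal", k = 1)
  calc <- fixture_calculator("einstein_crystal", k = 1, fixture = ein)
  sp <- phonon_spectrum(hessian(ein, calc, min_supercell_length = 6,
                                asr = FALSE), c(2, 2, 2))
  tp <- gibbs_ha(-10, sp, T = 300, p = 0, V = 100)
  expect_equal(tp$G, -10 + tp$F_vib, tolerance = 1e-12)
  tp2 <- gibbs_ha(-10, sp, T = 300, p = 1e-9, V = 100)
  expect_equal(tp2$G - tp$G, 1e-7, tolerance = 1e-6)
  tp0 <- gibbs_ha(-10, sp, T = 0, p = 0, V = 100)
  expect_equal(tp0$F_vib, f_vib(sp, 0), tolerance = 1e-12)
})

test_that("extensivity: doubling the cell doubles E_latt, ZPE and F_vib", {
  lj <- ar_lj()
  fcc <- relax(make_fixture("lj_fcc"), lj)$structure
  fc1 <- hessian(fcc, lj)
  sp1 <- phonon_spectrum(fc1, c(4, 4, 4))
  dbl <- make_supercell(fcc, c(2, 1, 1))
  fc2 <- hessian(dbl, lj)
  sp2 <- phonon_spectrum(fc2, c(2, 4, 4))
  expect_equal(calc_eval(lj, dbl)$energy, 2 * calc_eval(lj, fcc)$energy,
               tolerance = 1e-10)
  expect_equal(f_vib(sp2, 0) / (2 * f_vib(sp1, 0)), 1, tolerance = 1e-8)
  expect_equal(f_vib(sp2, 300) / (2 * f_vib(sp1, 300)), 1, tolerance = 1e-6)
})

test_that("Birch-Murnaghan fitting round-trips and tolerates noise", {
  dat <- make_eos_data(list(F0 = -1, V0 = 100, B0 = 0.5, B0p = 4))
  expect_equal(nrow(dat), 17)
  fit <- fit_birch_murnaghan(dat$V, dat$F)
  expect_lt(abs(fit$F0 + 1), 1e-6)
  expect_lt(abs(fit$V0 - 100) / 100, 1e-6)
  expect_lt(abs(fit$B0 - 0.5) / 0.5, 1e-6)
  expect_lt(abs(fit$B0p - 4) / 4, 1e-6)
  for (s in 1:20) {
    d <- make_eos_data(list(F0 = -1, V0 = 100, B0 = 0.5, B0p = 4),
                       noise = 1e-5, seed = s)
    f <- fit_birch_murnaghan(d$V, d$F)
    expect_lt(abs(f$V0 - 100) / 100, 0.001)
  }
  expect_error(fit_birch_murnaghan(seq(90, 110, length.out = 9),
                                   seq(9, 1, length.out = 9)),
               class = "csp_fit_failure")
  expect_error(fit_birch_murnaghan(c(90, 100, 110), c(1, 0, 1)), ">= 5")
})

test_that("QHA expands the LJ crystal on heating and lowers G with T", {
  lj <- pair_potential("lj", list("Ar-Ar" = c(eps = 0.1, sigma = 3.4)),
                       cutoff = 8)
  tc <- qha(make_fixture("lj_fcc", eps = 0.1), lj, T_list = c(0, 300),
            mesh = c(3, 3, 3))
  s <- tc$summary
  expect_gt(s$V[s$T == 300], s$V[s$T == 0])
  expect_true(all(diff(s$G) < 0))
  expect_length(tc$dropped, 0)
})

test_that("volume-independent frequencies give zero thermal expansion", {
  ein <- make_fixture("einstein_crystal", k = 1)
  comp <- composite_calculator(einstein_calculator(ein, 1),
                               eos_calculator(-1, cell_volume(ein$lattice),
                                              0.5))
  tc <- qha(ein, comp, T_list = c(0, 300), mesh = c(3, 3, 3),
            min_supercell_length = 6, asr = FALSE)
  s <- tc$summary
  expect_lt(max(abs(s$V - s$V[1])), 1e-6 * s$V[1])
  expect_true(all(diff(s$G) < 0))
})

test_that("heat capacity is the negative curvature of G, reaching Dulong-Petit", {
  Tg <- seq(100, 200, by = 10)
  a <- 3e-6
  expect_equal(heat_capacity(-a * Tg^2, Tg), 2 * a * Tg, tolerance = 1e-10)
  expect_equal(heat_capacity(5 - 0.01 * Tg, Tg), rep(0, length(Tg)),
               tolerance = 1e-10)
  expect_error(heat_capacity(Tg, Tg[c(1:9, 11)]), "uniform|length")
  # Einstein crystal at k_B T = 10 hbar w0: Cp -> 3 n k_B within 1%
  ein <- make_fixture("einstein_crystal", k = 1)
  calc <- fixture_calculator("einstein_crystal", k = 1, fixture = ein)
  sp <- phonon_spectrum(hessian(ein, calc, min_supercell_length = 6,
                                asr = FALSE), c(2, 2, 2))
  w0 <- attr(ein, "reference")$omega0
  Tdp <- cc$hbar * w0 * 10 / cc$k_B
  Tg2 <- seq(Tdp - 20, Tdp + 20, by = 10)
  G <- vapply(Tg2, function(T) f_vib(sp, T), 0)
  Cp <- heat_capacity(G, Tg2)
  expect_equal(Cp[3] / (3 * cc$k_B), 1, tolerance = 0.01)
})
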