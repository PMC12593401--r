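# molecular shells, n-mer enumeration and tethered sampling

test_that("molecular shell membership matches brute-force image enumeration", {
  m <- molecule_n2()
  cr <- generate_candidate(m, "P-1", 2, contact_criterion(0.8),
                           generation_config(), seed = 7)
  cr <- identify_molecules(cr)
  uw <- cspkit:::unwrap_molecules(cr)
  cell <- as.matrix(cr$lattice)
  # independent oracle: enumerate 3x3x3 images of every molecule
  brute_shell <- function(cutoff) {
    cen <- uw$frac_unwrapped[[1]] %*% cell
    cnt <- 0
    for (ml in seq_along(uw$molecules)) {
      for (i in -1:1) for (j in -1:1) for (k in -1:1) {
        if (ml == 1 && i == 0 && j == 0 && k == 0) next
        pos <- (uw$frac_unwrapped[[ml]] +
                  matrix(c(i, j, k), 2, 3, byrow = TRUE)) %*% cell
        dmin <- min(as.matrix(stats::dist(rbind(pos, cen)))[1:2, 3:4])
        if (dmin <= cutoff) cnt <- cnt + 1
      }
    }
    cnt + 1  # plus the central molecule
  }
  for (cutoff in c(3, 4.5, 6)) {
    expect_equal(length(molecular_shell(cr, 1, cutoff)), brute_shell(cutoff))
  }
  # below the nearest contact: shell is only the central molecule
  expect_equal(length(molecular_shell(cr, 1, 0.4)), 1)
  expect_error(molecular_shell(cr, 99, 5), "center")
  # two images of the same molecule can both be members
  members <- attr(molecular_shell(cr, 1, 6), "members")
  ids <- vapply(members, function(x) x$id, 0)
  expect_true(any(table(ids) > 1))
})

test_that("shell members are whole and unwrapped", {
  m <- molecule_n2()
  cr <- generate_candidate(m, "P21/c", 4, contact_criterion(0.75),
                           generation_config(max_attempts = 500), seed = 11)
  sh <- molecular_shell(identify_molecules(cr), 1, 5)
  for (mol in sh) {
    expect_equal(as.numeric(stats::dist(mol$positions)), 1.10,
                 tolerance = 1e-9)
  }
})

test_that("n-mer enumeration is ordered, deduplicated and deterministic", {
  m <- molecule_n2()
  cr <- identify_molecules(
    generate_candidate(m, "P-1", 2, contact_criterion(0.8),
                       generation_config(), seed = 7))
  nm <- enumerate_nmers(cr, 3, per_order_counts = c(1, 3, 2), seed = 3,
                        cutoff = 6)
  orders <- vapply(nm, function(x) x$order, 0L)
  expect_equal(orders, c(1L, 2L, 2L, 2L, 3L, 3L))
  expect_equal(length(nm[[1]]$molecules), 1)
  # the first dimer is the nearest-neighbour one
  sh <- molecular_shell(cr, 1, 6)
  dmin <- vapply(sh[-1], function(x) {
    cspkit:::min_cross_dist(x$positions, sh[[1]]$positions)
  }, 0)
  d_first <- cspkit:::min_cross_dist(nm[[2]]$molecules[[2]]$positions,
                                     nm[[2]]$molecules[[1]]$positions)
  expect_equal(d_first, min(dmin), tolerance = 1e-9)
  # asking for more combinations than exist returns all, without repeats
  nm2 <- enumerate_nmers(cr, 2, per_order_counts = c(1, 10000), seed = 1,
                         cutoff = 5)
  dimers <- Filter(function(x) x$order == 2, nm2)
  keyset <- vapply(dimers, function(d) {
    paste(round(d$molecules[[2]]$positions[1, ], 6), collapse = ",")
  }, "")
  expect_false(any(duplicated(keyset)))
  nm3 <- enumerate_nmers(cr, 3, per_order_counts = c(1, 3, 2), seed = 3,
                         cutoff = 6)
  expect_equal(length(nm3), length(nm))
})

test_that("tethered sampling is deterministic, bounded and convergent", {
  teach <- n2_teacher()
  cr <- identify_molecules(
    generate_candidate(molecule_n2(), "P-1", 2, contact_criterion(0.8),
                       generation_config(), seed = 7))
  dimer <- enumerate_nmers(cr, 2, per_order_counts = 1, seed = 1,
                           cutoff = 6)[[2]]
  x0 <- cspkit:::as_atoms(dimer)$positions
  st <- tether_settings(n_steps = 600, stride = 100, seed = 4)
  f1 <- tethered_sampling(dimer, teach, st)
  f2 <- tethered_sampling(dimer, teach, st)
  expect_identical(cspkit:::as_atoms(f1[[6]])$positions,
                   cspkit:::as_atoms(f2[[6]])$positions)
  expect_equal(length(f1), 6)
  # stiff tether bounds the excursion
  fs <- tethered_sampling(dimer, teach,
                          tether_settings(k_tether = 1000, n_steps = 2000,
                                          timestep = 0.05, stride = 200,
                                          seed = 4))
  expect_lt(max(vapply(fs, function(f) {
    max(abs(cspkit:::as_atoms(f)$positions - x0))
  }, 0)), 0.05)
  # T = 0 at a minimum: no drift
  m0 <- molecule(c("Ar", "Ar"), rbind(c(0, 0, 0), c(2^(1 / 6) * 3.4, 0, 0)))
  lj <- ar_lj(cutoff = 12, shift = FALSE)
  f0 <- tethered_sampling(m0, lj, tether_settings(k_tether = 0,
                                                  temperature = 0,
                                                  n_steps = 300, stride = 100,
                                                  seed = 1))
  expect_lt(max(abs(cspkit:::as_atoms(f0[[3]])$positions - m0$positions)),
            1e-6)
})

test_that("mean tether displacement decreases with spring constant", {
  teach <- n2_teacher()
  m <- molecule_n2()
  x0 <- m$positions
  md <- vapply(c(0.005, 0.05, 0.5), function(k) {
    fr <- tethered_sampling(m, teach,
                            tether_settings(k_tether = k, n_steps = 1500,
                                            timestep = 0.5, stride = 100,
                                            seed = 4))
    mean(vapply(fr, function(f) {
      sqrt(mean((cspkit:::as_atoms(f)$positions - x0)^2))
    }, 0))
  }, 0)
  expect_true(all(diff(md) < 0))
})
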