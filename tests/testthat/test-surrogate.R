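# descriptor construction and surrogate training

test_that("descriptors are invariant and vanish outside the cutoff", {
  b <- descriptor_basis("Ar", cutoff = 5)
  iso <- molecule("Ar", rbind(c(0, 0, 0)))
  expect_true(all(descriptors(iso, b) == 0))
  set.seed(9)
  env <- molecule(rep("Ar", 5), rbind(c(0, 0, 0), matrix(stats::runif(12, -3, 3), 4, 3)))
  X <- descriptors(env, b)
  R <- cspkit:::rotvec_matrix(c(0.4, -1.1, 0.6))
  env2 <- cspkit:::geom_set_positions(env, env$positions %*% t(R) + 5)
  expect_lt(max(abs(descriptors(env2, b) - X)), 1e-12)
  # permutation invariance of the per-atom sums
  perm <- c(3, 1, 5, 2, 4)
  env3 <- molecule(env$symbols[perm], env$positions[perm, ])
  expect_lt(max(abs(colSums(descriptors(env3, b)) - colSums(X))), 1e-12)
  # boundary: neighbour just beyond the cutoff contributes nothing
  far <- molecule(c("Ar", "Ar"), rbind(c(0, 0, 0), c(5.0001, 0, 0)))
  expect_true(all(descriptors(far, b) == 0))
  near <- molecule(c("Ar", "Ar"), rbind(c(0, 0, 0), c(4.999, 0, 0)))
  expect_true(any(descriptors(near, b) != 0))
  # smooth approach to zero at the boundary
  vals <- vapply(c(4.9, 4.95, 4.99), function(d) {
    max(abs(descriptors(molecule(c("Ar", "Ar"),
                                 rbind(c(0, 0, 0), c(d, 0, 0))), b)))
  }, 0)
  expect_true(all(diff(vals) < 0))
})

test_that("training interpolates representable labels and is deterministic", {
  b <- descriptor_basis("Ar", cutoff = 5, n_basis = 6)
  set.seed(3)
  w_true <- stats::rnorm(6)
  mk <- function() {
    n <- sample(2:4, 1)
    molecule(rep("Ar", n), matrix(stats::runif(3 * n, 0, 4), n, 3))
  }
  geoms <- replicate(25, mk(), simplify = FALSE)
  samples <- lapply(geoms, function(g) {
    X <- descriptors(g, b)
    labeled_sample(g, sum(X %*% w_true) + 2.5 * nrow(X))
  })
  mod <- train_surrogate(samples, basis = b, regularization = 1e-12,
                         force_weight = 0)
  resid <- vapply(seq_along(geoms), function(i) {
    surrogate_predict(mod, geoms[[i]])$energy - samples[[i]]$energy
  }, 0)
  expect_lt(max(abs(resid)), 1e-8)
  # duplicating samples does not change the exact fit
  mod2 <- train_surrogate(c(samples, samples), basis = b,
                          regularization = 1e-12, force_weight = 0)
  expect_lt(max(abs(mod$weights - mod2$weights)), 1e-8)
  mod3 <- train_surrogate(samples, basis = b, regularization = 1e-12,
                          force_weight = 0)
  expect_identical(mod$weights, mod3$weights)
  expect_error(train_surrogate(list()), "empty")
})

test_that("surrogate predictions are invariant and forces analytic", {
  set.seed(5)
  teach <- n2_teacher()
  geoms <- lapply(seq(3, 6, length.out = 20), function(s) {
    nmer(list(molecule_n2(),
              molecule(c("N", "N"), rbind(c(s, 0, 0), c(s, 0, 1.1)))))
  })
  samples <- label_with_teacher(geoms, teach)
  b <- descriptor_basis("N", cutoff = 5)
  mod <- train_surrogate(samples, basis = b)
  g <- geoms[[7]]
  at <- cspkit:::as_atoms(g)
  R <- cspkit:::rotvec_matrix(c(0.3, -0.2, 0.9))
  g2 <- cspkit:::geom_set_positions(g, at$positions %*% t(R) + 2)
  expect_lt(abs(surrogate_predict(mod, g)$energy -
                  surrogate_predict(mod, g2)$energy), 1e-10)
  sc <- surrogate_calculator(mod)
  fa <- calc_eval(sc, g, forces = TRUE)$forces
  fn <- cspkit:::numerical_forces(sc, g)
  expect_lt(max(abs(fa - fn)), 1e-6)
})

test_that("hold-out error decreases as the training set grows", {
  set.seed(17)
  teach <- n2_teacher()
  mk <- function(s) nmer(list(molecule_n2(),
                              molecule(c("N", "N"),
                                       rbind(c(s, 0.3, 0), c(s, 0.3, 1.1)))))
  train_geoms <- lapply(stats::runif(100, 3, 6), mk)
  hold_geoms <- lapply(stats::runif(30, 3, 6), mk)
  hold <- label_with_teacher(hold_geoms, teach)
  b <- descriptor_basis("N", cutoff = 5)
  mae <- vapply(c(10, 100), function(ntr) {
    mod <- train_surrogate(label_with_teacher(train_geoms[1:ntr], teach),
                           basis = b)
    mean(vapply(hold, function(s) {
      abs(surrogate_predict(mod, s$geometry)$energy - s$energy)
    }, 0))
  }, 0)
  expect_lt(mae[2], mae[1])
})

test_that("ensemble statistics use the sample standard deviation", {
  b <- descriptor_basis("N", cutoff = 5)
  mod <- train_surrogate(label_with_teacher(list(molecule_n2()), n2_teacher()),
                         basis = b)
  # identical models: zero spread
  p <- ensemble_predict(list(mod, mod, mod, mod), molecule_n2())
  expect_identical(p$E_std, 0)
  expect_error(ensemble_predict(list(mod), molecule_n2()), "single model")
  # hand sample-std check via biased models
  mods <- lapply(c(1.0, 1.2, 0.8, 1.0), function(sh) {
    m2 <- mod
    # shift every element bias by sh so prediction moves by n_atoms * sh
    nf <- length(b$elements) * b$n_basis
    idx <- seq_len(length(m2$weights) / (nf + 1)) * (nf + 1)
    m2$weights[idx] <- m2$weights[idx] + sh
    m2
  })
  p2 <- ensemble_predict(mods, molecule_n2())
  expect_equal(p2$E_std, stats::sd(c(1.0, 1.2, 0.8, 1.0) * 2),
               tolerance = 1e-10)
  # permutation of model order changes nothing
  p3 <- ensemble_predict(mods[c(3, 1, 4, 2)], molecule_n2())
  expect_equal(p3$E_mean, p2$E_mean, tolerance = 1e-12)
  expect_equal(p3$E_std, p2$E_std, tolerance = 1e-12)
})
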