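test_that("exact rank-1 structure is recovered", {
  grid <- seq(47, 82, by = 1)
  w <- curvecast:::trapezoid_weights(grid)
  phi <- sin(grid / 6) + 1
  phi <- phi / sqrt(sum(w * phi^2))
  mu <- 4 + 0.02 * (grid - 47)
  beta <- seq(-2, 2, length.out = 12)
  cs <- make_curve_set(outer(rep(1, 12), mu) + outer(beta, phi), grid)
  fb <- fit_fpca(cs, 1)
  expect_equal(fb$var_explained[1], 1.0, tolerance = 1e-8)
  expect_lt(max(abs(abs(fb$basis[, 1]) - abs(phi))), 1e-8)
  expect_lt(max(fb$resid_var_curve), 1e-12)
  expect_equal(unname(drop(fb$scores)), beta - mean(beta), tolerance = 1e-8)
})

test_that("identical curves give zero scores and the common mean", {
  grid <- seq(47, 82, by = 1)
  mu <- 4 + 0.02 * (grid - 47)
  cs <- make_curve_set(outer(rep(1, 6), mu), grid)
  fb <- fit_fpca(cs, 2)
  expect_equal(fb$mean_curve, mu)
  expect_true(all(fb$scores == 0))
  expect_true(all(fb$var_explained == 0))
})

test_that("basis, eigenvalues and scores match a dense eigendecomposition oracle", {
  set.seed(31)
  for (i in 1:20) {
    T_ <- sample(3:6, 1)
    G <- sample(5:9, 1)
    grid <- seq(47, 82, length.out = G)
    curves <- matrix(rnorm(T_ * G), T_, G)
    K <- T_ - 1
    fb <- fit_fpca(make_curve_set(curves, grid), K)
    or <- fpca_eigen_oracle(curves, grid)
    expect_equal(fb$var_explained,
                 (or$values / sum(or$values))[seq_len(K)], tolerance = 1e-8)
    for (k in seq_len(K)) {
      phi_o <- or$vectors[, k] / sqrt(or$w)
      sgn <- sign(sum(fb$basis[, k] * phi_o))
      expect_equal(fb$basis[, k], sgn * phi_o, tolerance = 1e-7)
      sc_o <- drop(or$centered %*% (or$w * phi_o)) * sgn
      expect_equal(unname(fb$scores[, k]), sc_o, tolerance = 1e-7)
    }
  }
})

test_that("basis is orthonormal, scores are centered and uncorrelated", {
  sim <- simulate_surface(generator_config(seed = 404))
  sc <- smooth_surface(log_transform(sim$surface))
  fb <- fit_fpca(sc, 3)
  w <- fb$weights
  gram <- t(fb$basis) %*% (w * fb$basis)
  expect_equal(gram, diag(3), tolerance = 1e-8, ignore_attr = TRUE)
  expect_lt(max(abs(colMeans(fb$scores))), 1e-8)
  cc <- stats::cor(fb$scores)
  expect_lt(max(abs(cc[upper.tri(cc)])), 1e-8)
  expect_true(all(diff(fb$var_explained) <= 1e-12))
  expect_true(all(fb$var_explained >= 0 & fb$var_explained <= 1))
  expect_lte(sum(fb$var_explained), 1 + 1e-12)
  expect_true(all(fb$resid_var_curve >= 0))
})

test_that("two equal-eigenvalue components split variance 50/50", {
  grid <- seq(47, 82, by = 1)
  w <- curvecast:::trapezoid_weights(grid)
  p1 <- orthon <- curvecast:::orthonormalize(cbind(grid - 64.5, (grid - 64.5)^2), w)
  beta <- cbind(c(1, -1, 1, -1, 1, -1, 1, -1), c(1, 1, -1, -1, 1, 1, -1, -1))
  cs <- make_curve_set(4 + beta %*% t(orthon), grid)
  fb <- fit_fpca(cs, 2)
  expect_equal(fb$var_explained, c(0.5, 0.5), tolerance = 1e-10)
})

test_that("reconstruction matches the dense product and full order is lossless", {
  sim <- simulate_surface(generator_config(seed = 405))
  sc <- smooth_surface(log_transform(sim$surface))
  fb <- fit_fpca(sc, 4)
  expect_equal(reconstruct(fb, rep(0, 4)), fb$mean_curve)
  set.seed(32)
  b <- rnorm(4)
  expect_equal(reconstruct(fb, b),
               drop(fb$mean_curve + fb$basis %*% b), tolerance = 1e-12)
  expect_error(reconstruct(fb, rnorm(3)), "length")
  # complete basis reproduces every training curve
  small <- make_curve_set(sc$curves[1:6, ], sc$grid)
  full <- fit_fpca(small, 5)
  for (t in 1:6) {
    expect_equal(reconstruct(full, t), small$curves[t, ], tolerance = 1e-6)
  }
})

test_that("Parseval: full-order score variance equals total curve variance", {
  set.seed(33)
  grid <- seq(47, 82, length.out = 8)
  curves <- matrix(rnorm(5 * 8), 5, 8)
  fb <- fit_fpca(make_curve_set(curves, grid), 4)
  w <- fb$weights
  Cm <- sweep(curves, 2, colMeans(curves))
  total <- sum(t(Cm^2) * w)
  expect_equal(sum(fb$scores^2), total, tolerance = 1e-6)
})

test_that("adding a constant shifts only the mean curve; refits are bit-identical", {
  sim <- simulate_surface(generator_config(seed = 406))
  sc <- smooth_surface(log_transform(sim$surface))
  fb1 <- fit_fpca(sc, 2)
  sc2 <- sc
  sc2$curves <- sc$curves + 1.5
  fb2 <- fit_fpca(sc2, 2)
  expect_equal(fb2$mean_curve, fb1$mean_curve + 1.5, tolerance = 1e-10)
  expect_equal(fb2$basis, fb1$basis, tolerance = 1e-8)
  expect_equal(fb2$scores, fb1$scores, tolerance = 1e-8)
  fb3 <- fit_fpca(sc, 2)
  expect_identical(fb3$basis, fb1$basis)
  expect_identical(fb3$scores, fb1$scores)
})

test_that("infeasible K is rejected", {
  sim <- simulate_surface(generator_config(seed = 407))
  sc <- smooth_surface(log_transform(sim$surface))
  expect_error(fit_fpca(sc, 0), "positive")
  expect_error(fit_fpca(sc, 52), "feasible")
})
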