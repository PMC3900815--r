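test_that("identical seed and config give bit-identical surfaces", {
  s1 <- simulate_surface(generator_config(seed = 77))
  s2 <- simulate_surface(generator_config(seed = 77))
  expect_identical(s1$surface$rates, s2$surface$rates)
  expect_identical(s1$truth$scores, s2$truth$scores)
  s3 <- simulate_surface(generator_config(seed = 78))
  expect_false(identical(s1$surface$rates, s3$surface$rates))
})

test_that("zero-noise, zero-component config yields constant years at exp(mu)", {
  cfg <- generator_config(basis_raw = list(), score_params = list(),
                          resid_raw = list(), resid_sd = numeric(0),
                          sigma_obs = 0, seed = 1)
  sim <- simulate_surface(cfg)
  r <- sim$surface$rates
  for (t in 2:nrow(r)) expect_equal(r[t, ], r[1, ])
  mids <- sim$truth$midpoints
  mu_mid <- cfg$mean_coef[1] + cfg$mean_coef[2] * (mids - 47) +
    cfg$mean_coef[3] * (mids - 47)^2
  expect_equal(unname(r[1, ]), exp(mu_mid), tolerance = 1e-10)
})

test_that("generated basis is orthonormal and truth is self-consistent", {
  sim <- simulate_surface(rank3_config(79))
  tr <- sim$truth
  w <- curvecast:::trapezoid_weights(tr$grid)
  B <- cbind(tr$basis, tr$resid_basis)
  expect_equal(t(B) %*% (w * B), diag(ncol(B)), tolerance = 1e-10,
               ignore_attr = TRUE)
  # surface log rates = truth at midpoints + stored noise draws
  T_ <- length(tr$config$years)
  expect_equal(log(sim$surface$rates),
               tr$truth_at_midpoints[seq_len(T_), ] + tr$noise,
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_true(all(sim$surface$rates > 0))
  expect_error(
    simulate_surface(generator_config(
      basis_raw = list(function(x) x, function(x) 2 * x),
      score_params = list(list(alpha = .3, beta = .05, phi_d = .9, l0 = 0,
                               b0 = .1, sigma = .1),
                          list(alpha = .3, beta = .05, phi_d = .9, l0 = 0,
                               b0 = .1, sigma = .1)))),
    "orthogonalizable")
})

test_that("fitted first-score variance matches the realized generating process", {
  cfg <- generator_config(years = 1802:2001, sigma_obs = 0.05,
                          resid_sd = c(0.005, 0.005), seed = 80)
  sim <- simulate_surface(cfg)
  sc <- smooth_surface(log_transform(sim$surface))
  fb <- fit_fpca(sc, 1)
  T_ <- 200
  true_scores <- sim$truth$scores[seq_len(T_), 1]
  v_true <- mean((true_scores - mean(true_scores))^2)
  v_fit <- mean((fb$scores[, 1] - mean(fb$scores[, 1]))^2)
  expect_lt(abs(v_fit / v_true - 1), 0.10)
})

test_that("coverage is monotone in the nominal level and 1 under zero noise", {
  cfg <- generator_config(seed = 81)
  cv80 <- coverage_experiment(cfg, replicates = 30, h = 10, level = 0.80,
                              seed = 81, horizons = c(1, 5, 10))
  cv99 <- coverage_experiment(cfg, replicates = 30, h = 10, level = 0.99,
                              seed = 81, horizons = c(1, 5, 10))
  expect_equal(cv80$n_failed, 0)
  expect_gt(cv99$overall, cv80$overall)
  # noiseless, structureless surface with a linear mean curve (which the
  # spline reproduces exactly): intervals collapse but still cover the truth
  cfg0 <- generator_config(
    mean_coef = c(4.0, 0.02, 0), basis_raw = list(), score_params = list(),
    resid_raw = list(), resid_sd = numeric(0), sigma_obs = 0, seed = 82)
  cv0 <- suppressWarnings(
    coverage_experiment(cfg0, replicates = 10, h = 5, level = 0.80,
                        seed = 82, horizons = c(1, 5), K = 1))
  expect_equal(cv0$overall, 1.0)
})

test_that("noise streams are independent: changing one preserves the others", {
  cfg <- generator_config(seed = 83)
  base <- simulate_surface(cfg)
  cfg2 <- cfg
  cfg2$sigma_obs <- 0
  quiet <- simulate_surface(cfg2)
  expect_identical(base$truth$scores, quiet$truth$scores)
  expect_identical(base$truth$resid_coefs, quiet$truth$resid_coefs)
  expect_equal(log(quiet$surface$rates),
               quiet$truth$truth_at_midpoints[1:52, ], tolerance = 1e-12,
               ignore_attr = TRUE)
})
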