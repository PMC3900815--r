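# Shared synthetic scenarios and small constructors used across the test
# files. All fixtures are generated in code; nothing is read from disk
# except the bundled example CSV.

# Rank-1 scenario: the default surface shape with one true component and
# small noise, for order-selection and variance-explained recovery.
rank1_config <- function(seed) {
  generator_config(resid_sd = c(0.005, 0.005), sigma_obs = 0.01, seed = seed)
}

# Rank-2 scenario: dominant damped trend plus one persistent level
# component, long record so the second component's signal is identifiable.
rank2_config <- function(seed) {
  generator_config(
    years = 1852:2001,
    basis_raw = list(function(x) 0.3 + exp(-0.5 * ((x - 63) / 10)^2),
                     function(x) x - 64.5),
    score_params = list(
      list(alpha = 0.3, beta = 0.05, phi_d = 0.9, l0 = 0, b0 = 0.30,
           sigma = 0.10),
      list(alpha = 0.9, beta = 1e-4, phi_d = 0.9, l0 = 0, b0 = 0,
           sigma = 0.20)),
    resid_raw = list(function(x) (x - 64.5)^2),
    resid_sd = 0.01, sigma_obs = 0.01, seed = seed)
}

# Rank-3 scenario: well-separated eigenvalues (roughly 5x/3x), components 2
# and 3 are persistent level processes whose displacement accumulates over a
# long record, so holding them out visibly hurts out-of-sample MISE.
rank3_config <- function(seed) {
  generator_config(
    years = 1802:2001,
    basis_raw = list(function(x) 0.3 + exp(-0.5 * ((x - 63) / 10)^2),
                     function(x) x - 64.5,
                     function(x) (x - 64.5)^2),
    score_params = list(
      list(alpha = 0.3, beta = 0.05, phi_d = 0.9, l0 = 0, b0 = 0.30,
           sigma = 0.10),
      list(alpha = 0.9, beta = 1e-4, phi_d = 0.9, l0 = 0, b0 = 0,
           sigma = 0.20),
      list(alpha = 0.9, beta = 1e-4, phi_d = 0.9, l0 = 0, b0 = 0,
           sigma = 0.13)),
    resid_raw = list(function(x) (x - 64.5)^3),
    resid_sd = 0.01, sigma_obs = 0.01, seed = seed)
}

# Bare smooth_curve_set from a curve matrix, for FPCA tests that need exact
# low-rank structure without running the smoother.
make_curve_set <- function(curves, grid, obs_var = rep(0, length(grid))) {
  structure(
    list(years = seq_len(nrow(curves)) + 1949L, grid = grid,
         curves = curves, obs_var = obs_var,
         midpoints = grid[round(seq(1, length(grid), length.out = 5))],
         smooth_params = data.frame(year = seq_len(nrow(curves)) + 1949L,
                                    lambda = NA_real_, edf = NA_real_,
                                    sigma2 = NA_real_),
         residuals = NULL, rate_unit = 1e5),
    class = "smooth_curve_set")
}

# Small wide CSV on disk for I/O tests; returns the path.
write_demo_csv <- function(rates, years, labels, path = tempfile(fileext = ".csv")) {
  df <- data.frame(age_group = labels, check.names = FALSE)
  for (i in seq_along(years)) df[[as.character(years[i])]] <- rates[i, ]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

# Independent dense FPCA oracle: eigendecomposition of the explicit
# quadrature-weighted covariance matrix of the centered curves.
fpca_eigen_oracle <- function(curves, grid) {
  w <- curvecast:::trapezoid_weights(grid)
  Cm <- sweep(curves, 2L, colMeans(curves))
  Cw <- sweep(Cm, 2L, sqrt(w), `*`)
  eg <- eigen(crossprod(Cw), symmetric = TRUE)
  list(values = eg$values, vectors = eg$vectors, w = w, centered = Cm)
}
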