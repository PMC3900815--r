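# Synthetic mortality-surface generator. Surfaces are drawn from exactly the
# functional model the pipeline assumes,
#   y_t(x_i) = mu(x_i) + sum_k beta_{t,k} phi_k(x_i) + e_t(x_i) + eps_{t,i},
# with damped-trend score processes, so ground truth (including future score
# paths and future smooth curves) is available for every stage's tests and
# for interval-calibration experiments. No registry data is bundled or used.

#' Configuration for the synthetic mortality-surface generator
#'
#' Defaults emulate a female breast-cancer-type mortality surface: 8
#' five-year age groups from 45--49 to 80--84, 52 annual observations, a
#' concave increasing mean log-rate curve (about 55 rising to 220 deaths per
#' 100,000 across the age range), one dominant component of variation peaked
#' at ages 60--70 whose score follows a damped-trend process with an initially
#' rising trend, two small white residual components forming the
#' model-residual variance \code{v(x)}, and observational noise of sd 0.04 on
#' the log scale.
#'
#' @param age_groups 2-column matrix of (low, high) age bounds.
#' @param years calendar years of the observed surface.
#' @param mean_coef coefficients (c0, c1, c2) of the mean log-rate curve
#'   \code{c0 + c1 (x - x0) + c2 (x - x0)^2}, \code{x0} = first midpoint,
#'   log deaths per 100,000.
#' @param basis_raw list of \code{K_true} functions of age; they are
#'   orthonormalized under grid quadrature before use.
#' @param score_params list of \code{K_true} lists with elements
#'   \code{alpha, beta, phi_d, l0, b0, sigma} -- the damped-trend process
#'   generating each score series.
#' @param resid_raw list of functions of age spanning the model-residual
#'   space (orthonormalized against the basis).
#' @param resid_sd per-component sd of the white residual coefficients.
#' @param sigma_obs observational noise sd (log scale).
#' @param grid_step age-grid step in years.
#' @param seed root seed; per-purpose streams (scores, residual, noise) are
#'   derived from it so toggling one noise source preserves the others.
#' @return an object of class \code{generator_config}.
#' @export
generator_config <- function(
    age_groups = cbind(seq(45, 80, by = 5), seq(49, 84, by = 5)),
    years = 1950:2001,
    mean_coef = c(4.0, 0.045, -0.00025),
    basis_raw = list(function(x) 0.3 + exp(-0.5 * ((x - 63) / 10)^2)),
    score_params = list(list(alpha = 0.3, beta = 0.05, phi_d = 0.9,
                             l0 = 0, b0 = 0.25, sigma = 0.12)),
    resid_raw = list(function(x) x - mean(range(x)),
                     function(x) (x - mean(range(x)))^2),
    resid_sd = c(0.05, 0.05),
    sigma_obs = 0.04,
    grid_step = 1,
    seed = 20100305) {
  K_true <- length(basis_raw)
  if (length(score_params) != K_true) {
    stop("need one score_params entry per basis function")
  }
  if (length(resid_sd) != length(resid_raw)) {
    stop("resid_sd must match resid_raw in length")
  }
  structure(
    list(age_groups = age_groups, years = as.integer(years),
         mean_coef = mean_coef, basis_raw = basis_raw, K_true = K_true,
         score_params = score_params, resid_raw = resid_raw,
         resid_sd = resid_sd, sigma_obs = sigma_obs, grid_step = grid_step,
         seed = as.integer(seed)),
    class = "generator_config")
}

# Derived, non-colliding seeds for the three randomness purposes.
stream_seed <- function(root, purpose) {
  offs <- c(scores = 11, resid = 23, noise = 37, future_noise = 53)
  as.integer((as.numeric(root) + offs[[purpose]] * 1000003) %% 2147483647)
}

# Damped-trend innovations recursion driven by given innovations; returns
# the observed series y_t = l_{t-1} + phi * b_{t-1} + eps_t.
simulate_ets_path <- function(innov, alpha, beta, phi_d, l0, b0, ...) {
  n <- length(innov)
  y <- numeric(n)
  l <- l0
  b <- b0
  for (t in seq_len(n)) {
    f <- l + phi_d * b
    y[t] <- f + innov[t]
    l <- f + alpha * innov[t]
    b <- phi_d * b + beta * innov[t]
  }
  y
}

#' Simulate a mortality surface with stored ground truth
#'
#' Builds log-rate truth curves \code{mu(x) + sum_k beta_{t,k} phi_k(x) +
#' e_t(x)} on a fine age grid for \code{T + h_future} years (score paths are
#' extended past the observed window so holdout truth exists), evaluates them
#' at the group midpoints, adds observational noise, and exponentiates to
#' rates per 100,000.
#'
#' @param cfg a \code{\link{generator_config}}.
#' @param h_future number of future years of truth to generate (default 20).
#' @return list with elements \code{surface} (a
#'   \code{\link{mortality_surface}}) and \code{truth} (class
#'   \code{synthetic_truth}): config, grid, \code{mean_curve}, \code{basis}
#'   (orthonormal, G x K), \code{resid_basis}, \code{scores}
#'   ((T+h) x K), \code{resid_coefs}, \code{truth_curves} ((T+h) x G),
#'   \code{future_curves} (h x G), \code{truth_at_midpoints}, \code{noise},
#'   \code{future_noise}, \code{v_curve} (implied model-residual variance).
#' @export
simulate_surface <- function(cfg, h_future = 20) {
  stopifnot(inherits(cfg, "generator_config"))
  mids <- (cfg$age_groups[, 1L] + cfg$age_groups[, 2L]) / 2
  rng <- range(mids)
  G <- round((rng[2L] - rng[1L]) / cfg$grid_step)
  grid <- seq(rng[1L], rng[2L], length.out = G + 1L)
  w <- trapezoid_weights(grid)
  T_ <- length(cfg$years)
  n_tot <- T_ + h_future

  mu <- cfg$mean_coef[1L] + cfg$mean_coef[2L] * (grid - mids[1L]) +
    cfg$mean_coef[3L] * (grid - mids[1L])^2

  basis <- if (cfg$K_true > 0) {
    orthonormalize(vapply(cfg$basis_raw, function(f) f(grid),
                          numeric(length(grid))), w)
  } else matrix(0, length(grid), 0L)
  resid_basis <- if (length(cfg$resid_raw) > 0) {
    orthonormalize(vapply(cfg$resid_raw, function(f) f(grid),
                          numeric(length(grid))), w, against = basis)
  } else matrix(0, length(grid), 0L)

  withr_seed <- function(s, expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
            else assign(".Random.seed", old, envir = globalenv()))
    set.seed(s)
    expr
  }

  scores <- withr_seed(stream_seed(cfg$seed, "scores"), {
    out <- matrix(0, n_tot, cfg$K_true)
    for (k in seq_len(cfg$K_true)) {
      p <- cfg$score_params[[k]]
      innov <- stats::rnorm(n_tot, 0, p$sigma)
      out[, k] <- do.call(simulate_ets_path, c(list(innov = innov), p))
    }
    out
  })
  resid_coefs <- withr_seed(stream_seed(cfg$seed, "resid"), {
    matrix(stats::rnorm(n_tot * length(cfg$resid_sd)), n_tot) %*%
      diag(cfg$resid_sd, nrow = length(cfg$resid_sd))
  })
  noise <- withr_seed(stream_seed(cfg$seed, "noise"), {
    matrix(stats::rnorm(T_ * length(mids), 0, cfg$sigma_obs), T_)
  })
  future_noise <- withr_seed(stream_seed(cfg$seed, "future_noise"), {
    matrix(stats::rnorm(h_future * length(mids), 0, cfg$sigma_obs), h_future)
  })

  truth_curves <- matrix(rep(mu, each = n_tot), n_tot) +
    scores %*% t(basis) + resid_coefs %*% t(resid_basis)
  truth_mid <- interp_rows(truth_curves, grid, mids)
  log_obs <- truth_mid[seq_len(T_), , drop = FALSE] + noise
  rates <- exp(log_obs)
  surface <- mortality_surface(rates, cfg$years, cfg$age_groups)

  v_curve <- drop((resid_basis^2) %*% (cfg$resid_sd^2))
  truth <- structure(
    list(config = cfg, grid = grid, mean_curve = mu, basis = basis,
         resid_basis = resid_basis, scores = scores,
         resid_coefs = resid_coefs, truth_curves = truth_curves,
         future_curves = truth_curves[T_ + seq_len(h_future), , drop = FALSE],
         future_years = max(cfg$years) + seq_len(h_future),
         truth_at_midpoints = truth_mid, noise = noise,
         future_noise = future_noise, v_curve = v_curve,
         midpoints = mids, h_future = h_future),
    class = "synthetic_truth")
  list(surface = surface, truth = truth)
}

#' Variance-explained proportions implied by a realized synthetic truth
#'
#' The proportions an exact functional principal components decomposition of
#' the noiseless truth curves over the observed window would report:
#' eigenvalue shares of the empirical covariance of the centered truth
#' curves under grid quadrature. Note these are properties of the realized
#' score paths, not of the generating parameters: score processes with
#' persistent dynamics produce sample paths that are correlated across
#' components, so the leading empirical component is in general a rotation
#' of the generating basis.
#'
#' @param truth a \code{synthetic_truth}.
#' @return numeric vector of eigenvalue-share proportions (all components).
#' @export
implied_var_explained <- function(truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  T_ <- length(truth$config$years)
  curves <- truth$truth_curves[seq_len(T_), , drop = FALSE]
  w <- trapezoid_weights(truth$grid)
  Cm <- sweep(curves, 2L, colMeans(curves))
  d2 <- svd(sweep(Cm, 2L, sqrt(w), `*`))$d^2
  d2 / sum(d2)
}

#' Empirical coverage of pipeline prediction intervals by simulation
#'
#' Repeatedly simulates a surface from \code{cfg}, runs the full pipeline
#' (smoothing, FPCA, damped-trend score forecasting, curve forecasting) and
#' records, per horizon and age-grid point, whether the target future value
#' lies inside the pointwise prediction interval. The default target is the
#' truth's future \emph{smooth} curve; correspondingly the intervals omit the
#' observational variance term. With \code{target = "observed"} the target is
#' a noisy future observation at the group midpoints and the observational
#' term is included.
#'
#' @param cfg a \code{\link{generator_config}}; replicate r uses root seed
#'   \code{seed + r - 1}.
#' @param replicates number of simulated surfaces (>= 100 recommended).
#' @param h maximum forecast horizon.
#' @param level nominal interval level (default 0.80).
#' @param seed root seed for the experiment (default \code{cfg$seed}).
#' @param horizons horizons at which coverage is recorded (default c(1, 10, 20),
#'   truncated to h).
#' @param K basis order used in the pipeline (default \code{K_true}).
#' @param target \code{"smooth"} or \code{"observed"}.
#' @return an object of class \code{coverage_result}: \code{coverage}
#'   (horizons x ages matrix), \code{by_horizon}, \code{overall},
#'   \code{level}, \code{n_used}, \code{n_failed}, \code{target}.
#' @export
coverage_experiment <- function(cfg, replicates = 500, h = 20, level = 0.80,
                                seed = cfg$seed, horizons = c(1, 10, 20),
                                K = NULL, target = c("smooth", "observed")) {
  stopifnot(inherits(cfg, "generator_config"))
  target <- match.arg(target)
  horizons <- horizons[horizons <= h]
  if (is.null(K)) K <- max(cfg$K_true, 1L)
  mids <- (cfg$age_groups[, 1L] + cfg$age_groups[, 2L]) / 2
  n_age <- if (target == "smooth") {
    # evaluated on the fine grid
    round((max(mids) - min(mids)) / cfg$grid_step) + 1L
  } else nrow(cfg$age_groups)
  hits <- matrix(0, length(horizons), n_age)
  n_ok <- 0L
  n_failed <- 0L
  for (r in seq_len(replicates)) {
    cfg_r <- cfg
    cfg_r$seed <- as.integer((as.numeric(seed) + r - 1) %% 2147483647)
    res <- tryCatch({
      sim <- simulate_surface(cfg_r, h_future = h)
      sc <- smooth_surface(log_transform(sim$surface),
                           grid_step = cfg$grid_step)
      fb <- fit_fpca(sc, K)
      mods <- lapply(seq_len(K), function(k)
        suppressWarnings(fit_ets_damped(fb$scores[, k])))
      fcst <- forecast_surface(fb, mods, sc, h = h, level = level,
                               include_obs_var = (target == "observed"))
      z <- stats::qnorm(1 - (1 - level) / 2)
      inmat <- matrix(0, length(horizons), n_age)
      for (j in seq_along(horizons)) {
        hz <- horizons[j]
        if (target == "smooth") {
          tr <- sim$truth$future_curves[hz, ]
          lo <- fcst$mean_log[hz, ] - z * sqrt(fcst$var_log[hz, ])
          up <- fcst$mean_log[hz, ] + z * sqrt(fcst$var_log[hz, ])
        } else {
          tr <- sim$truth$truth_at_midpoints[length(cfg$years) + hz, ] +
            sim$truth$future_noise[hz, ]
          v <- fcst$age_group_view
          lo <- log(v$lower_rate[hz, ])
          up <- log(v$upper_rate[hz, ])
        }
        # floating-point guard so degenerate zero-width intervals count a
        # numerically identical target as covered
        tol <- 1e-8 * pmax(1, abs(tr))
        inmat[j, ] <- as.numeric(tr >= lo - tol & tr <= up + tol)
      }
      inmat
    }, error = function(e) NULL)
    if (is.null(res)) {
      n_failed <- n_failed + 1L
    } else {
      hits <- hits + res
      n_ok <- n_ok + 1L
    }
  }
  if (n_ok == 0L) stop("all replicates failed")
  cov <- hits / n_ok
  structure(
    list(coverage = cov, horizons = horizons,
         by_horizon = rowMeans(cov), overall = mean(cov),
         level = level, n_used = n_ok, n_failed = n_failed, target = target),
    class = "coverage_result")
}

#' @export
print.generator_config <- function(x, ...) {
  cat("Synthetic surface generator:", nrow(x$age_groups), "age groups,",
      length(x$years), "years, K_true =", x$K_true,
      ", sigma_obs =", x$sigma_obs, ", seed =", x$seed, "\n")
  invisible(x)
}

#' @export
print.coverage_result <- function(x, ...) {
  cat(sprintf(
    "Empirical coverage of %.0f%% intervals (target: %s, %d replicates, %d failed)\n",
    100 * x$level, x$target, x$n_used, x$n_failed))
  print(data.frame(horizon = x$horizons,
                   coverage = round(x$by_horizon, 4)))
  cat("overall:", round(x$overall, 4), "\n")
  invisible(x)
}
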