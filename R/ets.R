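# Damped-trend exponential smoothing in innovations state-space form
# (additive error, additive damped trend, no season):
#   y_t   = l_{t-1} + phi_d * b_{t-1} + eps_t
#   l_t   = l_{t-1} + phi_d * b_{t-1} + alpha * eps_t
#   b_t   = phi_d * b_{t-1}           + beta  * eps_t
# with eps_t ~ N(0, sigma2). Each FPCA score series gets its own fit; the
# damping parameter phi_d < 1 makes long-horizon forecasts level off instead
# of extrapolating the trend indefinitely.

ets_filter <- function(y, alpha, beta, phi, l0, b0) {
  n <- length(y)
  e <- numeric(n)
  lv <- numeric(n)
  bv <- numeric(n)
  l <- l0
  b <- b0
  for (t in seq_len(n)) {
    f <- l + phi * b
    e[t] <- y[t] - f
    l <- f + alpha * e[t]
    b <- phi * b + beta * e[t]
    lv[t] <- l
    bv[t] <- b
  }
  list(e = e, level = lv, trend = bv)
}

#' Fit a damped-trend exponential smoothing model by maximum likelihood
#'
#' Maximizes the Gaussian innovations log-likelihood over the smoothing
#' parameters, the damping parameter and the initial states, using bounded
#' quasi-Newton optimization from a fixed list of five starting points (so
#' the fit is deterministic). Ties in likelihood are broken toward the
#' smallest \code{alpha}. Parameter bounds: \code{alpha} in [1e-4, 0.9999],
#' \code{beta} in [1e-4, alpha], \code{phi_d} in \code{phi_bounds} (default
#' [0.8, 0.98], the classical damping range).
#'
#' For series shorter than 8 observations the damping parameter is fixed at
#' 0.9 and only the smoothing parameters and initial states are estimated
#' (with a warning). A constant series returns a degenerate model
#' (\code{alpha} at its lower bound, zero trend, \code{sigma2 = 0}) with a
#' warning.
#'
#' @param series numeric vector (a score series), length >= 4.
#' @param phi_bounds length-2 bounds for the damping parameter.
#' @param fix_phi optional fixed damping value (e.g. 1 for an undamped
#'   linear trend); overrides \code{phi_bounds}.
#' @return an object of class \code{ets_damped}: \code{alpha}, \code{beta},
#'   \code{phi_d}, \code{l0}, \code{b0}, \code{sigma2} (mean squared one-step
#'   innovation), \code{loglik}, \code{fitted_states} (per-time level/trend),
#'   \code{residuals}, \code{last_level}, \code{last_trend}, \code{n}.
#' @export
fit_ets_damped <- function(series, phi_bounds = c(0.8, 0.98), fix_phi = NULL) {
  y <- as.numeric(series)
  n <- length(y)
  if (n < 4L) stop("need at least 4 observations to fit the damped-trend model")
  if (stats::sd(y) < 1e-12) {
    warning("degenerate (constant) series: returning a flat model")
    st <- ets_filter(y, 1e-4, 1e-4, 0.9, y[1L], 0)
    return(new_ets_damped(1e-4, 1e-4, 0.9, y[1L], 0, y, st))
  }
  if (n < 8L && is.null(fix_phi)) {
    warning("series has fewer than 8 observations: damping fixed at 0.9")
    fix_phi <- 0.9
  }

  b0_start <- (y[min(5L, n)] - y[1L]) / (min(5L, n) - 1L)
  sdy <- stats::sd(y)
  # fixed multi-start list: (alpha, beta/alpha ratio, phi_d, l0, b0)
  starts <- list(
    c(0.2, 0.10, 0.85, y[1L], b0_start),
    c(0.4, 0.30, 0.90, y[1L], b0_start),
    c(0.6, 0.10, 0.95, y[1L], b0_start),
    c(0.8, 0.30, 0.90, y[1L], 0),
    c(0.95, 0.05, 0.90, y[1L], b0_start))

  free_phi <- is.null(fix_phi)
  obj <- function(par) {
    alpha <- par[1L]
    beta <- max(par[2L] * alpha, 1e-4)
    phi <- if (free_phi) par[3L] else fix_phi
    st <- ets_filter(y, alpha, beta, phi, par[4L], par[5L])
    mse <- mean(st$e^2)
    if (!is.finite(mse)) return(1e12)
    0.5 * n * log(mse)
  }

  lower <- c(1e-4, 1e-4, if (free_phi) phi_bounds[1L], -Inf, -Inf)
  upper <- c(0.9999, 1, if (free_phi) phi_bounds[2L], Inf, Inf)
  sel <- if (free_phi) 1:5 else c(1:2, 4:5)

  fits <- lapply(starts, function(s) {
    p0 <- s[sel]
    o <- tryCatch(
      stats::optim(p0, function(p) { q <- s; q[sel] <- p; obj(q) },
                   method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(maxit = 500)),
      error = function(e) list(par = p0, value = Inf))
    full <- s
    full[sel] <- o$par
    list(par = full, value = o$value)
  })
  vals <- vapply(fits, `[[`, numeric(1), "value")
  alphas <- vapply(fits, function(f) f$par[1L], numeric(1))
  best_val <- min(vals)
  cand <- which(vals <= best_val + 1e-8)
  pick <- cand[which.min(alphas[cand])] # tie-break: smallest alpha
  p <- fits[[pick]]$par
  alpha <- p[1L]
  beta <- max(p[2L] * alpha, 1e-4)
  phi <- if (free_phi) p[3L] else fix_phi
  st <- ets_filter(y, alpha, beta, phi, p[4L], p[5L])
  new_ets_damped(alpha, beta, phi, p[4L], p[5L], y, st)
}

new_ets_damped <- function(alpha, beta, phi, l0, b0, y, st) {
  n <- length(y)
  sigma2 <- mean(st$e^2)
  loglik <- if (sigma2 > 0) -n / 2 * (log(2 * pi * sigma2) + 1) else Inf
  structure(
    list(alpha = alpha, beta = beta, phi_d = phi, l0 = l0, b0 = b0,
         sigma2 = sigma2, loglik = loglik,
         fitted_states = data.frame(level = st$level, trend = st$trend),
         residuals = st$e, last_level = st$level[n], last_trend = st$trend[n],
         n = n),
    class = "ets_damped")
}

#' Forecast from a fitted damped-trend exponential smoothing model
#'
#' Closed-form h-step forecasts: the mean at lead \code{j} is
#' \code{l_T + (phi + phi^2 + ... + phi^j) * b_T}; the variance at lead
#' \code{j} is \code{sigma2 * (1 + sum_{i=1}^{j-1} c_i^2)} with
#' \code{c_i = alpha + beta * (phi + ... + phi^i)}. Interval bounds are
#' Gaussian quantiles around the mean.
#'
#' @param m an \code{ets_damped} model.
#' @param h forecast horizon (integer >= 1).
#' @param level nominal interval coverage in (0, 1) (default 0.80).
#' @return an object of class \code{score_forecast}: \code{h}, \code{means},
#'   \code{variances}, \code{level}, \code{lower}, \code{upper}.
#' @export
forecast_ets <- function(m, h, level = 0.80) {
  stopifnot(inherits(m, "ets_damped"))
  if (!(is.numeric(h) && h >= 1 && h == round(h))) stop("h must be a positive integer")
  if (!(is.numeric(level) && level > 0 && level < 1)) {
    stop("level must be in (0, 1)")
  }
  cumphi <- cumsum(m$phi_d ^ seq_len(h))
  means <- m$last_level + cumphi * m$last_trend
  cj <- m$alpha + m$beta * cumphi
  variances <- m$sigma2 * (1 + c(0, cumsum(cj^2))[seq_len(h)])
  z <- stats::qnorm(1 - (1 - level) / 2)
  structure(
    list(h = h, means = means, variances = variances, level = level,
         lower = means - z * sqrt(variances),
         upper = means + z * sqrt(variances)),
    class = "score_forecast")
}

#' Dump fitted model parameters as flat key-value text
#'
#' @param m an \code{ets_damped} model.
#' @param path output file path.
#' @return invisibly NULL.
#' @export
write_ets <- function(m, path) {
  stopifnot(inherits(m, "ets_damped"))
  keys <- c("alpha", "beta", "phi_d", "l0", "b0", "sigma2", "loglik")
  writeLines(paste0(keys, " = ",
                    vapply(keys, function(k) formatC(m[[k]], digits = 12,
                                                     format = "g"),
                           character(1))),
             path)
  invisible(NULL)
}

#' @export
print.ets_damped <- function(x, ...) {
  cat(sprintf(
    "Damped-trend ETS: alpha=%.4f beta=%.4f phi_d=%.4f sigma2=%.5g loglik=%.3f\n",
    x$alpha, x$beta, x$phi_d, x$sigma2, x$loglik))
  invisible(x)
}

#' @export
print.score_forecast <- function(x, ...) {
  cat("Score forecast, h =", x$h, "at level", x$level, "\n")
  print(data.frame(h = seq_len(x$h), mean = x$means, var = x$variances,
                   lower = x$lower, upper = x$upper))
  invisible(x)
}
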