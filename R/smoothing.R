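# Penalized-spline smoothing of one year's log mortality-age profile.
#
# The smoother is a cubic B-spline basis with knots at the age midpoints and
# a second-difference penalty on the coefficients (a P-spline), fit by
# penalized weighted least squares:
#     minimize  (y - B c)' W (y - B c) + lambda * c' D'D c
# where D is the second-difference matrix. The penalty null space contains
# all linear functions, so as lambda -> Inf the fit tends to the weighted
# least-squares line.

# B-spline design matrices: knot sequence = age midpoints extended by three
# extra knots on each side at the boundary spacing.
pspline_design <- function(midpoints, x) {
  d1 <- midpoints[2L] - midpoints[1L]
  dA <- midpoints[length(midpoints)] - midpoints[length(midpoints) - 1L]
  knots <- c(midpoints[1L] - (3:1) * d1, midpoints,
             midpoints[length(midpoints)] + (1:3) * dA)
  splines::splineDesign(knots, x, ord = 4L, outer.ok = FALSE)
}

second_diff_matrix <- function(nb) {
  diff(diag(nb), differences = 2L)
}

# Fit machinery shared by smooth_year and the cached fast path in
# smooth_surface. Returns, for one penalty value, the linear maps from data
# to (coefficients, fitted values at observation points, curve on grid) plus
# the effective degrees of freedom.
pspline_maps <- function(B, Bg, D, w, lambda) {
  M <- crossprod(B, w * B) + lambda * crossprod(D)
  coef_map <- solve(M, t(B * w)) # nb x n: c = coef_map %*% y
  fit_map <- B %*% coef_map      # n x n hat matrix
  list(coef_map = coef_map, fit_map = fit_map, grid_map = Bg %*% coef_map,
       edf = sum(diag(fit_map) * 1))
}

gcv_lambda_grid <- function(bounds = c(-4, 4), n = 25L) {
  10 ^ seq(bounds[1L], bounds[2L], length.out = n)
}

#' Smooth one year's log mortality profile over age
#'
#' Fits a penalized cubic spline (knots at the age midpoints, second-difference
#' coefficient penalty) to the observed log rates of a single year and
#' evaluates it on a fine age grid. With \code{penalty = "auto"} the penalty is
#' chosen by generalized cross-validation over a logarithmic grid
#' (\code{10^-4} to \code{10^4}, 25 steps; ties broken toward the smoother
#' fit). The observational error variance is estimated from the residual sum
#' of squares divided by the residual degrees of freedom.
#'
#' @param log_y log rates at the age midpoints (may contain \code{NA}).
#' @param midpoints age midpoints (defines the knots).
#' @param grid fine age grid to evaluate the curve on.
#' @param penalty nonnegative number, or \code{"auto"} for GCV.
#' @param weights optional nonnegative observation weights (default uniform);
#'   supply inverse-variance weights when death counts are available.
#' @return list with \code{curve} (on grid), \code{penalty_used}, \code{edf},
#'   \code{sigma2} (residual variance estimate), \code{fitted} and
#'   \code{residuals} at the observed midpoints, and \code{obs_var}
#'   (\code{sigma2} replicated over the grid).
#' @export
smooth_year <- function(log_y, midpoints, grid, penalty = "auto",
                        weights = NULL) {
  ok <- is.finite(log_y)
  if (sum(ok) < 4L) {
    stop("insufficient data: need at least 4 non-missing ages, have ", sum(ok))
  }
  w <- if (is.null(weights)) rep(1, sum(ok)) else weights[ok]
  B <- pspline_design(midpoints, midpoints[ok])
  Bg <- pspline_design(midpoints, grid)
  D <- second_diff_matrix(ncol(B))
  y <- log_y[ok]
  n <- length(y)

  eval_one <- function(lambda) {
    m <- pspline_maps(B, Bg, D, w, lambda)
    fit <- drop(m$fit_map %*% y)
    rss <- sum(w * (y - fit)^2)
    list(maps = m, fit = fit, rss = rss,
         gcv = n * rss / max(n - m$edf, 1e-8)^2)
  }

  if (identical(penalty, "auto")) {
    best <- NULL
    for (lambda in gcv_lambda_grid()) {
      cand <- eval_one(lambda)
      if (is.null(best) || cand$gcv <= best$gcv) { # ties -> larger lambda
        best <- cand
        best$lambda <- lambda
      }
    }
  } else {
    stopifnot(is.numeric(penalty), penalty >= 0)
    best <- eval_one(penalty)
    best$lambda <- penalty
  }
  sigma2 <- best$rss / max(n - best$maps$edf, 0.1)
  list(curve = drop(best$maps$grid_map %*% y),
       penalty_used = best$lambda,
       edf = best$maps$edf,
       sigma2 = sigma2,
       fitted = best$fit,
       residuals = y - best$fit,
       ages_used = midpoints[ok],
       obs_var = rep(sigma2, length(grid)))
}

#' Smooth every year of a log-rate matrix onto a shared age grid
#'
#' Applies \code{\link{smooth_year}} to each calendar year, aligning all
#' curves on one uniform grid spanning the age-midpoint range. The
#' observational error variance is pooled across years: squared residuals at
#' the midpoints are averaged over years (with a degrees-of-freedom
#' correction), then regressed on age with the same spline smoother to give a
#' single per-age variance curve.
#'
#' @param m a \code{log_rate_matrix} from \code{\link{log_transform}}.
#' @param grid_step grid spacing in years of age (default 1).
#' @param penalty per-year penalty: a number, or \code{"auto"} for GCV.
#' @param weights optional T x A matrix of observation weights.
#' @return an object of class \code{smooth_curve_set}: \code{years},
#'   \code{grid}, \code{curves} (T x G), \code{obs_var} (length-G variance
#'   curve), \code{midpoints}, \code{smooth_params} (per-year lambda, edf,
#'   sigma2), \code{residuals} (T x A at midpoints).
#' @export
smooth_surface <- function(m, grid_step = 1, penalty = "auto", weights = NULL) {
  stopifnot(inherits(m, "log_rate_matrix"))
  T_ <- length(m$years)
  if (T_ < 2L) stop("need at least 2 years to smooth a surface")
  mids <- m$age_midpoints
  rng <- range(mids)
  G <- round((rng[2L] - rng[1L]) / grid_step)
  grid <- seq(rng[1L], rng[2L], length.out = G + 1L)

  A <- length(mids)
  curves <- matrix(NA_real_, T_, length(grid))
  resid <- matrix(NA_real_, T_, A)
  params <- data.frame(year = m$years, lambda = NA_real_, edf = NA_real_,
                       sigma2 = NA_real_)

  # Cache per missing-pattern linear maps so the common all-observed case
  # solves the penalized systems once per lambda, not once per year.
  cache <- new.env(parent = emptyenv())
  lambdas <- if (identical(penalty, "auto")) gcv_lambda_grid() else penalty
  get_maps <- function(ok, w) {
    key <- paste0(paste(as.integer(ok), collapse = ""), "|",
                  paste(signif(w, 8), collapse = ","))
    if (!is.null(cache[[key]])) return(cache[[key]])
    B <- pspline_design(mids, mids[ok])
    Bg <- pspline_design(mids, grid)
    D <- second_diff_matrix(ncol(B))
    maps <- lapply(lambdas, function(l) pspline_maps(B, Bg, D, w, l))
    cache[[key]] <- maps
    maps
  }

  for (t in seq_len(T_)) {
    y_full <- m$logrates[t, ]
    ok <- is.finite(y_full)
    if (sum(ok) < 4L) {
      stop("insufficient data in year ", m$years[t],
           ": need at least 4 non-missing ages, have ", sum(ok))
    }
    w <- if (is.null(weights)) rep(1, sum(ok)) else weights[t, ok]
    maps <- get_maps(ok, w)
    y <- y_full[ok]
    n <- length(y)
    best <- NULL
    for (i in seq_along(lambdas)) {
      fit <- drop(maps[[i]]$fit_map %*% y)
      rss <- sum(w * (y - fit)^2)
      gcv <- n * rss / max(n - maps[[i]]$edf, 1e-8)^2
      if (is.null(best) || gcv <= best$gcv) {
        best <- list(i = i, fit = fit, rss = rss, gcv = gcv)
      }
    }
    mp <- maps[[best$i]]
    curves[t, ] <- drop(mp$grid_map %*% y)
    resid[t, ok] <- y - best$fit
    params$lambda[t] <- lambdas[best$i]
    params$edf[t] <- mp$edf
    params$sigma2[t] <- best$rss / max(n - mp$edf, 0.1)
  }

  # Pooled observational variance curve: mean squared residual per age,
  # inflated by the average residual-df ratio, then smoothed over age.
  msr <- colMeans(resid^2, na.rm = TRUE)
  mean_edf <- mean(params$edf)
  infl <- A / max(A - mean_edf, 0.5)
  s2 <- msr * infl
  s2[!is.finite(s2)] <- mean(s2[is.finite(s2)])
  ov <- if (all(s2 < 1e-14)) {
    rep(0, length(grid))
  } else {
    pmax(smooth_year(s2, mids, grid, penalty = "auto")$curve, 0)
  }

  structure(
    list(years = m$years, grid = grid, curves = curves, obs_var = ov,
         midpoints = mids, smooth_params = params, residuals = resid,
         rate_unit = m$rate_unit),
    class = "smooth_curve_set")
}

#' @export
print.smooth_curve_set <- function(x, ...) {
  cat("Smooth log-mortality curves:", length(x$years), "years on",
      length(x$grid), "age grid points [", min(x$grid), "-", max(x$grid), "]\n")
  cat("  median GCV penalty:", stats::median(x$smooth_params$lambda),
      " median edf:", round(stats::median(x$smooth_params$edf), 2), "\n")
  invisible(x)
}
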