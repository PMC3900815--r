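#' Forecast future mortality-age curves with prediction intervals
#'
#' Combines per-component score forecasts with the FPCA basis:
#' the forecast log curve at horizon \code{j} is
#' \code{mu(x) + sum_k betahat_{T+j,k} phi_k(x)}, and its pointwise variance
#' is the sum of three components: the score-forecast variance propagated
#' through the basis (\code{sum_k phi_k(x)^2 Var(betahat_{T+j,k})}), the
#' model-residual variance curve \code{v(x)}, and the observational error
#' variance \code{sigma^2(x)}. Both variance curves are treated as constant
#' over the forecast horizon. Rate-scale bounds are the exponentials of the
#' log-scale Gaussian bounds (quantile mapping), and the point forecast on
#' the rate scale is \code{exp(mean_log)} -- the median of the implied
#' lognormal, not its mean.
#'
#' @param b an \code{fpca_basis}.
#' @param models list of K fitted \code{ets_damped} models, one per basis
#'   function (in component order).
#' @param c the \code{smooth_curve_set} the basis was fitted to (supplies the
#'   observational variance curve and the age midpoints).
#' @param h forecast horizon in years.
#' @param level nominal pointwise interval coverage (default 0.80, as in the
#'   forecast figures).
#' @param include_model_var include the model-residual variance \code{v(x)}
#'   in the interval variance (default TRUE).
#' @param include_obs_var include the observational variance
#'   \code{sigma^2(x)} (default TRUE; set FALSE when the target of the
#'   interval is the future smooth curve rather than a future observation).
#' @return an object of class \code{curve_forecast}: \code{grid},
#'   \code{years} (calendar years T+1..T+h), \code{mean_log}, \code{var_log}
#'   and its components \code{score_var}, \code{model_var}, \code{obs_var}
#'   (all h x G), \code{level}, \code{mean_rate}, \code{lower_rate},
#'   \code{upper_rate} (h x G, deaths per 100,000), \code{age_group_view}.
#' @export
forecast_surface <- function(b, models, c, h, level = 0.80,
                             include_model_var = TRUE,
                             include_obs_var = TRUE) {
  stopifnot(inherits(b, "fpca_basis"), inherits(c, "smooth_curve_set"))
  if (!is.list(models)) models <- list(models)
  if (length(models) != b$K) {
    stop("need one fitted score model per basis function: have ",
         length(models), ", K = ", b$K)
  }
  G <- length(b$grid)
  fc <- lapply(models, forecast_ets, h = h, level = level)
  score_means <- do.call(cbind, lapply(fc, `[[`, "means"))     # h x K
  score_vars <- do.call(cbind, lapply(fc, `[[`, "variances"))  # h x K

  mean_log <- matrix(rep(b$mean_curve, each = h), h, G) +
    score_means %*% t(b$basis)
  score_var <- score_vars %*% t(b$basis^2)
  model_var <- if (include_model_var) {
    matrix(rep(b$resid_var_curve, each = h), h, G)
  } else matrix(0, h, G)
  obs_var <- if (include_obs_var) {
    matrix(rep(c$obs_var, each = h), h, G)
  } else matrix(0, h, G)
  var_log <- score_var + model_var + obs_var

  z <- stats::qnorm(1 - (1 - level) / 2)
  lower_log <- mean_log - z * sqrt(var_log)
  upper_log <- mean_log + z * sqrt(var_log)

  out <- structure(
    list(grid = b$grid, years = max(b$years) + seq_len(h), h = h,
         mean_log = mean_log, var_log = var_log,
         score_var = score_var, model_var = model_var, obs_var = obs_var,
         level = level,
         mean_rate = exp(mean_log), lower_rate = exp(lower_log),
         upper_rate = exp(upper_log),
         rate_unit = b$rate_unit, midpoints = c$midpoints,
         score_forecasts = fc),
    class = "curve_forecast")
  out$age_group_view <- evaluate_at_midpoints(out, c$midpoints)
  out
}

#' Evaluate a curve forecast at the original age-group midpoints
#'
#' Linear interpolation of the mean and interval bounds (rate scale) at each
#' midpoint, for comparison against observed group rates.
#'
#' @param f a \code{curve_forecast}.
#' @param midpoints age midpoints, all within the grid range.
#' @return list with \code{midpoints} and h x A matrices \code{mean_rate},
#'   \code{lower_rate}, \code{upper_rate}, \code{mean_log}.
#' @export
evaluate_at_midpoints <- function(f, midpoints) {
  stopifnot(inherits(f, "curve_forecast"))
  list(midpoints = midpoints,
       mean_rate = interp_rows(f$mean_rate, f$grid, midpoints),
       lower_rate = interp_rows(f$lower_rate, f$grid, midpoints),
       upper_rate = interp_rows(f$upper_rate, f$grid, midpoints),
       mean_log = interp_rows(f$mean_log, f$grid, midpoints))
}

#' Write the forecast variance decomposition to CSV
#'
#' Long CSV with columns \code{year, age, score_var, model_var, obs_var}
#' (log-scale variances on the fine grid).
#'
#' @param path output path.
#' @param f a \code{curve_forecast}.
#' @return invisibly the written data frame.
#' @export
write_forecast_variance <- function(path, f) {
  stopifnot(inherits(f, "curve_forecast"))
  G <- length(f$grid)
  df <- data.frame(
    year = rep(f$years, each = G),
    age = rep(f$grid, times = f$h),
    score_var = as.vector(t(f$score_var)),
    model_var = as.vector(t(f$model_var)),
    obs_var = as.vector(t(f$obs_var)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' @export
print.curve_forecast <- function(x, ...) {
  cat("Curve forecast:", x$h, "years (", min(x$years), "-", max(x$years),
      ") at level", x$level, "\n")
  v <- x$age_group_view
  last <- x$h
  cat("  final-year rates per 100,000 at group midpoints:\n")
  print(round(rbind(mean = v$mean_rate[last, ], lower = v$lower_rate[last, ],
                    upper = v$upper_rate[last, ]), 1))
  invisible(x)
}
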