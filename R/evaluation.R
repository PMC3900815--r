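#' Integrated squared forecast error between two curves
#'
#' Trapezoidal quadrature of the squared difference over the age range,
#' normalized by the range length, so two curves differing by a constant
#' \code{delta} everywhere give \code{delta^2}. Units: squared log-rate.
#'
#' @param forecast,realized numeric curves on the same grid.
#' @param grid the shared age grid.
#' @return nonnegative scalar.
#' @export
isfe <- function(forecast, realized, grid) {
  if (length(forecast) != length(grid) || length(realized) != length(grid)) {
    stop("curves and grid must have the same length")
  }
  w <- trapezoid_weights(grid)
  sum(w * (forecast - realized)^2) / (max(grid) - min(grid))
}

#' Select the basis order by out-of-sample integrated squared forecast error
#'
#' Holds out the last \code{holdout} years, fits the full pipeline
#' (smoothing, FPCA, damped-trend score models) on the training window for
#' each candidate order K, forecasts the holdout horizons, and scores each
#' forecast curve against the holdout year's smooth curve with
#' \code{\link{isfe}}. The mean ISFE over horizons (MISE) selects K; ties
#' break toward the smaller (more parsimonious) order.
#'
#' @param m a \code{log_rate_matrix}.
#' @param candidate_orders integer vector of K values to compare.
#' @param holdout number of final years to hold out (default 10).
#' @param horizons horizons (subset of \code{1:holdout}) at which ISFE is
#'   computed; default all of \code{1:holdout}.
#' @param grid_step,penalty passed to \code{\link{smooth_surface}}.
#' @param phi_bounds damping bounds passed to \code{\link{fit_ets_damped}}.
#' @param adequacy_tol if positive, select the smallest K whose MISE is
#'   within this relative tolerance of the minimum (off by default, 0).
#' @return an object of class \code{evaluation_report}: \code{candidate_orders}
#'   (sorted), \code{holdout_years}, \code{horizons}, \code{isfe} (K x
#'   horizon matrix), \code{mise_by_K}, \code{selected_K}, \code{skipped}.
#' @export
evaluate_orders <- function(m, candidate_orders, holdout = 10, horizons = NULL,
                            grid_step = 1, penalty = "auto",
                            phi_bounds = c(0.8, 0.98), adequacy_tol = 0) {
  stopifnot(inherits(m, "log_rate_matrix"))
  T_ <- length(m$years)
  H <- as.integer(holdout)
  if (H < 1L || H >= T_) stop("holdout must be in 1..(T-1)")
  if (is.null(horizons)) horizons <- seq_len(H)
  horizons <- sort(unique(as.integer(horizons)))
  if (any(horizons < 1L | horizons > H)) stop("horizons must lie in 1..holdout")
  ks <- sort(unique(as.integer(candidate_orders)))
  T_train <- T_ - H
  kmax <- T_train - 1L
  feasible <- ks <= kmax
  if (!any(feasible)) {
    stop("no feasible candidate order: need K <= T_train - 1 = ", kmax,
         " with T_train = ", T_train, " training years")
  }
  skipped <- ks[!feasible]
  if (length(skipped)) {
    warning("candidate order(s) ", paste(skipped, collapse = ", "),
            " skipped: exceed feasibility bound K <= ", kmax)
  }
  ks <- ks[feasible]

  train <- structure(
    list(logrates = m$logrates[seq_len(T_train), , drop = FALSE],
         years = m$years[seq_len(T_train)], age_midpoints = m$age_midpoints,
         missing = m$missing[seq_len(T_train), , drop = FALSE],
         rate_unit = m$rate_unit),
    class = "log_rate_matrix")
  sc_train <- smooth_surface(train, grid_step = grid_step, penalty = penalty)

  # holdout truth: smooth each held-out year with the same smoother settings
  hold_curves <- matrix(NA_real_, H, length(sc_train$grid))
  for (j in seq_len(H)) {
    hold_curves[j, ] <- smooth_year(m$logrates[T_train + j, ],
                                    m$age_midpoints, sc_train$grid,
                                    penalty = penalty)$curve
  }

  err <- matrix(NA_real_, length(ks), length(horizons),
                dimnames = list(K = ks, horizon = horizons))
  for (i in seq_along(ks)) {
    fb <- fit_fpca(sc_train, ks[i])
    mods <- lapply(seq_len(ks[i]),
                   function(k) suppressWarnings(
                     fit_ets_damped(fb$scores[, k], phi_bounds = phi_bounds)))
    fcst <- forecast_surface(fb, mods, sc_train, h = H)
    for (j in seq_along(horizons)) {
      hz <- horizons[j]
      err[i, j] <- isfe(fcst$mean_log[hz, ], hold_curves[hz, ], sc_train$grid)
    }
  }
  mise <- rowMeans(err)
  if (adequacy_tol > 0) {
    ok <- mise <= min(mise) * (1 + adequacy_tol)
    selected <- ks[which(ok)[1L]]
  } else {
    selected <- ks[which.min(mise)] # which.min takes the first -> smaller K
  }
  structure(
    list(candidate_orders = ks, holdout_years = m$years[T_train + seq_len(H)],
         horizons = horizons, isfe = err, mise_by_K = stats::setNames(mise, ks),
         selected_K = selected, skipped = skipped),
    class = "evaluation_report")
}

#' Write an evaluation report to CSV
#'
#' @param r an \code{evaluation_report}.
#' @param isfe_path per-(K, horizon) ISFE table; \code{summary_path}
#'   per-K MISE with the selected flag. Either may be NULL.
#' @param summary_path see above.
#' @return invisibly NULL.
#' @export
write_evaluation <- function(r, isfe_path = NULL, summary_path = NULL) {
  stopifnot(inherits(r, "evaluation_report"))
  if (!is.null(isfe_path)) {
    df <- expand.grid(K = r$candidate_orders, horizon = r$horizons)
    df$isfe <- as.vector(r$isfe)
    utils::write.csv(df, isfe_path, row.names = FALSE)
  }
  if (!is.null(summary_path)) {
    utils::write.csv(
      data.frame(K = r$candidate_orders, mise = unname(r$mise_by_K),
                 selected = r$candidate_orders == r$selected_K),
      summary_path, row.names = FALSE)
  }
  invisible(NULL)
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("Basis-order evaluation over holdout years",
      min(x$holdout_years), "-", max(x$holdout_years), "\n")
  print(data.frame(K = x$candidate_orders, MISE = unname(x$mise_by_K),
                   selected = x$candidate_orders == x$selected_K))
  invisible(x)
}
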