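#' Functional principal components decomposition of smooth curves
#'
#' Decomposes a set of smooth log-mortality curves into a mean curve plus
#' \code{K} orthonormal basis functions (eigenfunctions of the empirical
#' covariance operator under trapezoidal grid quadrature) with per-year
#' scores:
#'   \deqn{f_t(x) = \mu(x) + \sum_k \beta_{t,k} \phi_k(x) + e_t(x).}
#' The scores of distinct components are empirically uncorrelated, which is
#' what licenses forecasting each score series with its own univariate time
#' series model. Computation goes through the singular value decomposition of
#' the centered, quadrature-weighted curve matrix rather than an explicit
#' covariance matrix.
#'
#' Sign convention: each basis function is scaled so its quadrature integral
#' is positive (first nonzero element positive if the integral is ~0), making
#' refits bit-reproducible.
#'
#' @param c a \code{smooth_curve_set} from \code{\link{smooth_surface}}.
#' @param K number of basis functions, \code{1 <= K <= min(T-1, G)}.
#' @return an object of class \code{fpca_basis}: \code{grid},
#'   \code{mean_curve}, \code{basis} (G x K), \code{scores} (T x K),
#'   \code{var_explained} (length K), \code{eigenvalues} (all T-1 or G, for
#'   diagnostics), \code{resid_var_curve} (length G, denominator T),
#'   \code{K}, \code{years}, \code{weights} (quadrature weights).
#' @export
fit_fpca <- function(c, K) {
  stopifnot(inherits(c, "smooth_curve_set"))
  curves <- c$curves
  T_ <- nrow(curves)
  G <- ncol(curves)
  if (T_ < 2L) stop("need at least 2 curves")
  if (!(is.numeric(K) && length(K) == 1L && K >= 1 && K == round(K))) {
    stop("K must be a positive integer")
  }
  if (K > min(T_ - 1L, G)) {
    stop("K = ", K, " exceeds the feasible order min(T-1, G) = ",
         min(T_ - 1L, G))
  }
  w <- trapezoid_weights(c$grid)
  mu <- colMeans(curves)
  Cm <- sweep(curves, 2L, mu)
  sw <- sqrt(w)
  Cw <- sweep(Cm, 2L, sw, `*`)
  sv <- svd(Cw)
  d2 <- sv$d^2
  total <- sum(d2)

  basis <- matrix(0, G, K)
  scores <- matrix(0, T_, K)
  if (total > 1e-290) {
    for (k in seq_len(K)) {
      phi <- sv$v[, k] / sw
      s <- sum(w * phi)
      flip <- if (abs(s) > 1e-12) s < 0 else {
        nz <- phi[abs(phi) > 1e-12]
        length(nz) > 0 && nz[1L] < 0
      }
      if (flip) phi <- -phi
      basis[, k] <- phi
      # scores are quadrature inner products <f_t - mu, phi_k>
      scores[, k] <- drop(Cw %*% (sw * phi))
    }
    ve <- d2[seq_len(K)] / total
  } else {
    # zero-variance curve set: keep requested order, all structure degenerate
    for (k in seq_len(K)) basis[k, k] <- 1 / sqrt(w[k])
    ve <- rep(0, K)
  }
  resid <- Cm - scores %*% t(basis)
  structure(
    list(grid = c$grid, mean_curve = mu, basis = basis, scores = scores,
         var_explained = ve, eigenvalues = d2 / T_,
         resid_var_curve = colMeans(resid^2), K = K, years = c$years,
         weights = w, total_variance = total,
         obs_var = c$obs_var, midpoints = c$midpoints,
         rate_unit = c$rate_unit),
    class = "fpca_basis")
}

#' Proportion of curve variance explained by each component
#'
#' Proportion \code{k} is the k-th eigenvalue over the total variance of the
#' centered curves under grid quadrature.
#'
#' @param b an \code{fpca_basis}.
#' @return numeric vector of K proportions (non-increasing, each in [0,1]).
#' @export
variance_explained <- function(b) {
  stopifnot(inherits(b, "fpca_basis"))
  b$var_explained
}

#' Reconstruct a curve from scores
#'
#' Returns \code{mu(x) + sum_k beta_k phi_k(x)} on the grid.
#'
#' @param b an \code{fpca_basis}.
#' @param scores either a single year index (integer in \code{1..T}) or a
#'   numeric score vector of length K.
#' @return numeric curve on \code{b$grid}.
#' @export
reconstruct <- function(b, scores) {
  stopifnot(inherits(b, "fpca_basis"))
  if (length(scores) == 1L && scores == round(scores) &&
      scores >= 1 && scores <= nrow(b$scores)) {
    scores <- b$scores[scores, ]
  }
  if (length(scores) != b$K) {
    stop("score vector has length ", length(scores), ", expected K = ", b$K)
  }
  drop(b$mean_curve + b$basis %*% scores)
}

#' Export an FPCA basis and scores to CSV
#'
#' @param b an \code{fpca_basis}.
#' @param basis_path,scores_path output CSV paths (either may be NULL).
#' @return invisibly NULL.
#' @export
write_fpca <- function(b, basis_path = NULL, scores_path = NULL) {
  stopifnot(inherits(b, "fpca_basis"))
  if (!is.null(basis_path)) {
    df <- data.frame(age = b$grid, mean = b$mean_curve)
    for (k in seq_len(b$K)) df[[paste0("phi_", k)]] <- b$basis[, k]
    utils::write.csv(df, basis_path, row.names = FALSE)
  }
  if (!is.null(scores_path)) {
    df <- data.frame(year = b$years)
    for (k in seq_len(b$K)) df[[paste0("beta_", k)]] <- b$scores[, k]
    utils::write.csv(df, scores_path, row.names = FALSE)
  }
  invisible(NULL)
}

#' @export
print.fpca_basis <- function(x, ...) {
  cat("Functional PCA basis: K =", x$K, "components,",
      nrow(x$scores), "years\n")
  cat("  variance explained:",
      paste0(sprintf("%.1f%%", 100 * x$var_explained), collapse = ", "), "\n")
  invisible(x)
}
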