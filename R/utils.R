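#' Trapezoidal quadrature weights
#'
#' Weights \code{w} such that \code{sum(w * f)} approximates the integral of
#' \code{f} over the range of \code{grid}. All inner products, norms and
#' integrated errors in the package use these weights, so quadrature is
#' consistent across modules.
#'
#' @param grid numeric vector of strictly increasing evaluation points.
#' @return numeric vector of weights, same length as \code{grid}.
#' @keywords internal
trapezoid_weights <- function(grid) {
  n <- length(grid)
  if (n < 2L) stop("grid must have at least 2 points")
  d <- diff(grid)
  if (any(d <= 0)) stop("grid must be strictly increasing")
  w <- numeric(n)
  w[1L] <- d[1L] / 2
  w[n] <- d[n - 1L] / 2
  if (n > 2L) w[2:(n - 1L)] <- (d[-1L] + d[-(n - 1L)]) / 2
  w
}

#' Gram-Schmidt orthonormalization under grid quadrature
#'
#' Orthonormalizes the columns of \code{mat} with respect to the inner product
#' \code{<f,g> = sum(w * f * g)}, optionally against an already-orthonormal
#' set in \code{against}.
#'
#' @param mat G x J matrix of function values on the grid.
#' @param w quadrature weights.
#' @param against optional G x J0 matrix of orthonormal columns to project out.
#' @return G x J matrix with quadrature-orthonormal columns.
#' @keywords internal
orthonormalize <- function(mat, w, against = NULL) {
  mat <- as.matrix(mat)
  out <- matrix(0, nrow(mat), ncol(mat))
  prev <- against
  for (j in seq_len(ncol(mat))) {
    v <- mat[, j]
    if (!is.null(prev)) {
      for (i in seq_len(ncol(prev))) v <- v - sum(w * v * prev[, i]) * prev[, i]
    }
    nrm <- sqrt(sum(w * v * v))
    if (!is.finite(nrm) || nrm < 1e-8) {
      stop("basis functions are not orthogonalizable (column ", j,
           " is numerically dependent on the preceding ones)")
    }
    v <- v / nrm
    out[, j] <- v
    prev <- if (is.null(prev)) out[, j, drop = FALSE] else cbind(prev, v)
  }
  out
}

# 32-bit FNV-1a hash of a string; used to stamp output bundles with the
# resolved configuration that produced them.
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "\n")
  b <- utf8ToInt(s)
  h <- 2166136261
  mulmod32 <- function(a, m) {
    lo <- a %% 65536
    hi <- (a - lo) / 65536
    (((hi * m) %% 65536) * 65536 + lo * m) %% 4294967296
  }
  for (byte in b) {
    lo8 <- h %% 256
    h <- h - lo8 + bitwXor(as.integer(lo8), as.integer(byte))
    h <- mulmod32(h, 16777619)
  }
  lo <- h %% 65536
  sprintf("%04x%04x", (h - lo) / 65536, lo)
}

# Linear interpolation of each row of `mat` (defined on `grid`) at `xout`.
interp_rows <- function(mat, grid, xout) {
  if (any(xout < min(grid) - 1e-9) || any(xout > max(grid) + 1e-9)) {
    stop("interpolation points outside the grid range [",
         min(grid), ", ", max(grid), "]")
  }
  t(apply(mat, 1L, function(row) stats::approx(grid, row, xout = xout)$y))
}
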