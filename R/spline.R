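#' Cubic smoothing spline with an explicit roughness trade-off
#'
#' Fits the natural cubic smoothing spline `f` minimizing
#' \deqn{p \sum_j |y_j - f(x_j)|^2 + (1 - p) \int |f''(t)|^2 dt,}
#' the classic Reinsch form in which `p = 1` interpolates the data exactly
#' and `p = 0` degenerates to the least-squares straight line.
#'
#' The fit is computed from the banded normal equations of the natural-spline
#' basis: with `Q` the second-difference operator and `R` the energy Gram
#' matrix of the interior second derivatives, the fitted values are
#' `a = y - (1 - p) Q [pR + (1-p)Q'Q]^{-1} Q' y`, which is well defined for
#' every `p` in `[0, 1]` including both endpoints.
#'
#' @param x Numeric vector of strictly increasing data sites.
#' @param y Numeric vector of data values, same length as `x`.
#' @param p Smoothing parameter in `[0, 1]`.
#' @return An object of class `kin_spline` with elements `x`, `fitted`
#'   (the spline evaluated at the sites) and `d2` (second derivatives at the
#'   sites), usable with [predict()].
#' @examples
#' x <- seq_len(50)
#' y <- sin(x / 8) + rnorm(50, sd = 0.05)
#' f <- smoothing_spline(x, y, p = 0.99)
#' predict(f, c(1.5, 10.25))
#' @export
smoothing_spline <- function(x, y, p) {
  if (!is.numeric(x) || !is.numeric(y) || length(x) != length(y)) {
    stop_validation("`x` and `y` must be numeric vectors of equal length.")
  }
  n <- length(x)
  if (n < 3L) stop_validation("smoothing spline needs at least 3 points.")
  if (any(diff(x) <= 0)) stop_validation("data sites must be strictly increasing.")
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1) {
    stop_validation("smoothing parameter `p` must be a single value in [0, 1].")
  }

  h <- diff(x)
  # Q: n x (n-2) second-difference operator; R: (n-2) x (n-2) energy matrix
  # (gamma' R gamma = integral of f''^2 for the natural spline).
  Q <- matrix(0, n, n - 2L)
  idx <- seq_len(n - 2L)
  Q[cbind(idx, idx)] <- 1 / h[idx]
  Q[cbind(idx + 1L, idx)] <- -(1 / h[idx] + 1 / h[idx + 1L])
  Q[cbind(idx + 2L, idx)] <- 1 / h[idx + 1L]
  R <- matrix(0, n - 2L, n - 2L)
  R[cbind(idx, idx)] <- (h[idx] + h[idx + 1L]) / 3
  if (n > 3L) {
    j <- seq_len(n - 3L)
    R[cbind(j, j + 1L)] <- h[j + 1L] / 6
    R[cbind(j + 1L, j)] <- h[j + 1L] / 6
  }

  A <- p * R + (1 - p) * crossprod(Q)
  gt <- solve(A, crossprod(Q, y))
  fitted <- as.vector(y - (1 - p) * (Q %*% gt))
  d2 <- c(0, p * as.vector(gt), 0) # natural boundary: f'' = 0 at the ends

  structure(list(x = x, fitted = fitted, d2 = d2),
            class = "kin_spline")
}

#' Evaluate a fitted smoothing spline
#'
#' @param object A `kin_spline` from [smoothing_spline()].
#' @param newx Sites at which to evaluate (defaults to the data sites).
#' @param ... Unused.
#' @return Numeric vector of spline values. Outside the data range the
#'   spline is extended linearly (natural boundary conditions).
#' @export
predict.kin_spline <- function(object, newx = object$x, ...) {
  x <- object$x
  a <- object$fitted
  g <- object$d2
  n <- length(x)
  i <- findInterval(newx, x, all.inside = TRUE)
  h <- x[i + 1L] - x[i]
  u <- (newx - x[i]) / h
  v <- 1 - u
  v * a[i] + u * a[i + 1L] +
    h^2 / 6 * ((v^3 - v) * g[i] + (u^3 - u) * g[i + 1L])
}

#' Smooth a backbone curve coordinate-wise
#'
#' Applies [smoothing_spline()] to each Cartesian coordinate of a sampled 3D
#' curve, with the sample index as the data site.  Because the same linear
#' smoother acts on all three coordinates, the operation commutes with
#' rotations, translations and scalings of the curve.
#'
#' @param curve Numeric matrix with one row per sample and columns x, y, z.
#' @param p Smoothing parameter in `[0, 1]`; see [smoothing_spline()].
#' @return Matrix of the same shape: the smoothed curve at the same sites.
#' @examples
#' th <- seq(0, pi, length.out = 50)
#' noisy <- cbind(cos(th), sin(th), 0) + matrix(rnorm(150, sd = 0.01), 50)
#' smooth_curve(noisy, p = 0.99)
#' @export
smooth_curve <- function(curve, p = 0.99) {
  curve <- as_curve_matrix(curve)
  apply(curve, 2L, function(y) smoothing_spline(seq_len(nrow(curve)), y, p)$fitted)
}
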