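# Kinematic surfaces: an n x n matrix of curvature or torsion values over
# (arm index s, normalized time t).  Rows index time, columns arm index.

#' Construct a kinematic surface
#'
#' @param values Nonnegative numeric matrix; rows = time grid, columns =
#'   arm-index grid.
#' @param quantity `"curvature"` or `"torsion"`.
#' @param s_axis,t_axis Grid coordinates in `[0, 1]` (defaults: uniform).
#' @return A `kin_surface` object.
#' @export
kin_surface <- function(values, quantity = c("curvature", "torsion"),
                        s_axis = NULL, t_axis = NULL) {
  quantity <- match.arg(quantity)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (anyNA(values) || any(!is.finite(values))) {
    stop_validation("surface values must be finite.")
  }
  if (any(values < 0)) stop_validation("surface values must be nonnegative.")
  s_axis <- s_axis %||% seq(0, 1, length.out = ncol(values))
  t_axis <- t_axis %||% seq(0, 1, length.out = nrow(values))
  if (length(s_axis) != ncol(values) || length(t_axis) != nrow(values)) {
    stop_validation("axis lengths must match the value matrix.")
  }
  dimnames(values) <- NULL
  structure(list(values = values, quantity = quantity,
                 s_axis = as.numeric(s_axis), t_axis = as.numeric(t_axis)),
            class = "kin_surface")
}

#' @export
print.kin_surface <- function(x, ...) {
  cat(sprintf("<kin_surface: %s, %d x %d (time x arm index), range [%.4g, %.4g]>\n",
              x$quantity, nrow(x$values), ncol(x$values),
              min(x$values), max(x$values)))
  invisible(x)
}

#' @describeIn kin_surface Long-format view: one row per grid cell with
#'   columns `s`, `t`, `value`, `quantity`.
#' @param x A `kin_surface`.
#' @param ... Unused.
#' @export
tidy.kin_surface <- function(x, ...) {
  tibble(
    s = rep(x$s_axis, each = length(x$t_axis)),
    t = rep(x$t_axis, times = length(x$s_axis)),
    value = as.vector(x$values),
    quantity = x$quantity
  )
}

# Total mass of a surface: Riemann sum of the values times the cell area of
# the uniform grid.  This is the quantity the Gaussian weights must add up to.
surface_mass <- function(surface) {
  ds <- if (length(surface$s_axis) > 1L) diff(surface$s_axis[1:2]) else 1
  dt <- if (length(surface$t_axis) > 1L) diff(surface$t_axis[1:2]) else 1
  sum(surface$values) * ds * dt
}

# Curvature/torsion profiles for one movement: resample each frame to n
# uniform points, normalize arm length to 1, smooth coordinate-wise, then
# apply the discrete kappa/tau estimators.  Returns m x n matrices.
movement_profiles <- function(curve_list, n, p) {
  prof <- lapply(curve_list, function(pts) {
    u <- resample_uniform(pts, n = n)
    len <- curve_length(u)
    if (len == 0) stop_validation("zero-length curve in movement.")
    u <- u / len
    if (p < 1) u <- smooth_curve(u, p = p)
    list(kappa = curvature_profile(u), tau = suppressWarnings(torsion_profile(u)))
  })
  list(
    kappa = do.call(rbind, lapply(prof, `[[`, "kappa")),
    tau = do.call(rbind, lapply(prof, `[[`, "tau"))
  )
}

# Resample an m x n profile matrix to n_out x n along the time axis with the
# same smoothing-spline machinery used along the arm, then clip the small
# negative undershoots a spline can produce.
resample_time_axis <- function(mat, times, n_out, p) {
  m <- nrow(mat)
  if (m == n_out && isTRUE(all.equal(times, seq(0, 1, length.out = m)))) {
    sm <- mat
  } else {
    sites <- 1 + times * (m - 1) # map normalized times onto the index scale
    target <- seq(1, m, length.out = n_out)
    sm <- apply(mat, 2L, function(y) {
      predict(smoothing_spline(sites, y, p), target)
    })
  }
  pmax(sm, 0)
}

#' Build curvature and torsion surfaces for each movement
#'
#' Converts a sequence of 3D backbone curves into a pair of `n` by `n`
#' surfaces giving curvature and torsion as a function of arm index and
#' normalized time.  Each frame is uniformly resampled, normalized to unit
#' arm length, and smoothed coordinate-wise by a cubic smoothing spline;
#' curvature and torsion profiles are then estimated by the three-point
#' circumcircle and five-point osculating-plane stencils, and the time axis
#' is resampled from `m` frames to `n` rows with the same spline machinery.
#' Because curvature and torsion are intrinsic, the surfaces are invariant
#' under rigid motions of the input.
#'
#' The distal `tip_exclude` fraction of the arm, where tracked tip values
#' are noisy outliers analyzed separately, is replaced by a flat fill of the
#' last retained arm-index column.
#'
#' @param curves Movement table (see [as_movement_tbl()]).
#' @param n Grid resolution (points per curve and time samples), default 100.
#' @param p Spline smoothing parameter in `[0, 1]` (see [smoothing_spline()]).
#' @param tip_exclude Fraction of the distal arm to flat-fill, in `[0, 0.5)`.
#' @return Tibble with one row per movement and quantity: columns
#'   `movement_id`, `quantity`, `n_frames`, and `surface` (a list-column of
#'   [kin_surface] objects).
#' @examples
#' mv <- sim_movement(gaussian_units(0.3, 0.5, 0.5, 0.01, 0.02), n = 40, m = 12)
#' build_surfaces(mv$curves, n = 40)
#' @export
build_surfaces <- function(curves, n = 100L, p = 0.99, tip_exclude = 0.1) {
  if (tip_exclude < 0 || tip_exclude >= 0.5) {
    stop_validation("`tip_exclude` must be in [0, 0.5).")
  }
  mv <- movement_frames(curves)
  purrr::imap_dfr(mv, function(seq, id) {
    prof <- movement_profiles(seq$curves, n = n, p = p)
    surfs <- lapply(list(curvature = prof$kappa, torsion = prof$tau),
                    function(mat) {
      v <- resample_time_axis(mat, seq$times, n_out = n, p = p)
      v <- flat_fill_tip(v, tip_exclude)
      v
    })
    tibble(
      movement_id = id,
      quantity = c("curvature", "torsion"),
      n_frames = length(seq$curves),
      surface = list(
        kin_surface(surfs$curvature, "curvature"),
        kin_surface(surfs$torsion, "torsion")
      )
    )
  })
}

# Replace the distal `frac` of arm-index columns by the last retained column.
flat_fill_tip <- function(values, frac) {
  if (frac <= 0) return(values)
  n <- ncol(values)
  s <- seq(0, 1, length.out = n)
  keep <- which(s <= 1 - frac)
  jmax <- max(keep)
  if (jmax < n) values[, (jmax + 1L):n] <- values[, jmax]
  values
}

# Convenience accessor: the pair of surfaces of one movement from the tibble
# returned by build_surfaces().
surface_pair <- function(surfaces, movement_id) {
  rows <- surfaces[surfaces$movement_id == movement_id, ]
  if (nrow(rows) == 0L) stop_validation("movement not found in surface table.")
  list(curvature = rows$surface[[match("curvature", rows$quantity)]],
       torsion = rows$surface[[match("torsion", rows$quantity)]])
}
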