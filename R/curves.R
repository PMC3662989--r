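# Backbone curves and movement tables.
#
# A single arm configuration ("backbone curve") is an n x 3 numeric matrix of
# ordered 3D points, base to tip.  A movement is stored tidily as a long
# tibble with columns movement_id, frame_index, point_index, x, y, z -- the
# same layout as the on-disk curve-sequence file.

#' Coerce a curve to a numeric point matrix
#'
#' Accepts an `n x 3` matrix or a data frame with columns `x`, `y`, `z`
#' (ordered base to tip) and returns a plain numeric matrix.
#'
#' @param curve Matrix or data frame describing one backbone curve.
#' @return Numeric matrix with columns x, y, z.
#' @export
as_curve_matrix <- function(curve) {
  if (is.data.frame(curve)) {
    missing <- setdiff(c("x", "y", "z"), names(curve))
    if (length(missing)) {
      stop_validation(paste0("curve data frame lacks column(s): ",
                             paste(missing, collapse = ", ")))
    }
    curve <- cbind(curve$x, curve$y, curve$z)
  }
  curve <- as.matrix(curve)
  if (ncol(curve) != 3L) stop_validation("a curve must have 3 coordinate columns.")
  if (!is.numeric(curve) || anyNA(curve) || any(!is.finite(curve))) {
    stop_validation("curve coordinates must be finite numbers.")
  }
  storage.mode(curve) <- "double"
  colnames(curve) <- c("x", "y", "z")
  curve
}

#' Total arclength of a sampled curve
#'
#' @param curve Curve matrix or data frame (see [as_curve_matrix()]).
#' @return Length of the piecewise-linear interpolant of the samples.
#' @export
curve_length <- function(curve) {
  p <- as_curve_matrix(curve)
  sum(sqrt(rowSums((p[-1L, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2)))
}

#' Resample a curve uniformly by arclength
#'
#' Places `n` points at equal arclength spacing along the piecewise-linear
#' interpolant of the input points.  The first and last input points are
#' preserved exactly; an input that is already `n` uniformly spaced points is
#' reproduced to rounding error.
#'
#' @param curve Ordered 3D point list (matrix or data frame), at least two
#'   distinct points.
#' @param n Number of output samples (>= 2; curvature and torsion profiles
#'   additionally need n >= 7).
#' @return `n x 3` matrix of uniformly spaced points.
#' @examples
#' seg <- rbind(c(0, 0, 0), c(1, 0, 0))
#' resample_uniform(seg, n = 11)
#' @export
resample_uniform <- function(curve, n = 100L) {
  p <- as_curve_matrix(curve)
  # drop consecutive duplicates: they carry no arclength
  if (nrow(p) > 1L) {
    keep <- c(TRUE, rowSums((p[-1L, , drop = FALSE] -
                             p[-nrow(p), , drop = FALSE])^2) > 0)
    p <- p[keep, , drop = FALSE]
  }
  if (nrow(p) < 2L) stop_validation("degenerate curve: fewer than 2 distinct points.")
  if (!is.numeric(n) || length(n) != 1L || n < 2L) {
    stop_validation("`n` must be a single count >= 2.")
  }
  n <- as.integer(n)
  seg <- sqrt(rowSums((p[-1L, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2))
  s <- c(0, cumsum(seg))
  target <- seq(0, s[length(s)], length.out = n)
  out <- vapply(1:3, function(j) approx(s, p[, j], xout = target)$y,
                numeric(n))
  out[1L, ] <- p[1L, ]
  out[n, ] <- p[nrow(p), ]
  colnames(out) <- c("x", "y", "z")
  out
}

#' Validate and normalize a movement table
#'
#' Checks the tidy curve-sequence layout (`movement_id`, `frame_index`,
#' `point_index`, `x`, `y`, `z`), orders rows, and verifies that every
#' movement has at least 3 frames and a consistent number of points per
#' frame.
#'
#' @param curves Movement table.
#' @return The validated tibble, ordered by movement, frame and point.
#' @export
as_movement_tbl <- function(curves) {
  required <- c("movement_id", "frame_index", "point_index", "x", "y", "z")
  missing <- setdiff(required, names(curves))
  if (length(missing)) {
    stop_validation(paste0("movement table lacks column(s): ",
                           paste(missing, collapse = ", ")))
  }
  curves <- dplyr::arrange(as_tibble(curves), .data$movement_id,
                           .data$frame_index, .data$point_index)
  if (anyNA(curves[required])) stop_validation("movement table contains missing values.")
  check <- curves |>
    dplyr::group_by(.data$movement_id) |>
    dplyr::summarise(
      m = dplyr::n_distinct(.data$frame_index),
      uniform = length(unique(table(.data$frame_index))) == 1L,
      .groups = "drop"
    )
  if (any(check$m < 3L)) {
    stop_validation("every movement needs at least 3 frames.")
  }
  if (any(!check$uniform)) {
    stop_validation("all frames of a movement must have the same number of points.")
  }
  curves
}

# Split a validated movement table into per-movement lists of curve matrices
# plus normalized times in [0, 1] (each movement's time axis is normalized
# independently, so movements of different durations share a common grid).
movement_frames <- function(curves) {
  curves <- as_movement_tbl(curves)
  split(curves, curves$movement_id) |>
    lapply(function(mv) {
      frames <- split(mv, mv$frame_index)
      f <- as.numeric(names(frames))
      list(
        curves = lapply(frames, as_curve_matrix),
        times = if (length(f) > 1L) (f - min(f)) / (max(f) - min(f)) else 0
      )
    })
}

# Assemble a list of curve matrices into the tidy movement layout.
frames_to_tbl <- function(curve_list, movement_id = "movement") {
  purrr::imap_dfr(curve_list, function(p, i) {
    tibble(
      movement_id = movement_id,
      frame_index = if (is.character(i)) as.integer(i) else as.integer(i),
      point_index = seq_len(nrow(p)),
      x = p[, 1L], y = p[, 2L], z = p[, 3L]
    )
  })
}
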