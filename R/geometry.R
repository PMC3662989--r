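# Discrete differential geometry of sampled space curves: curvature from the
# circumcircle of three successive samples, torsion from the angle between
# the osculating planes of successive sample triangles.

cross3 <- function(u, v) {
  c(u[2L] * v[3L] - u[3L] * v[2L],
    u[3L] * v[1L] - u[1L] * v[3L],
    u[1L] * v[2L] - u[2L] * v[1L])
}

#' Curvature from the circumcircle of three points
#'
#' Estimates the curvature at the middle of three successive samples as the
#' inverse radius of the circle through them,
#' \eqn{\kappa = 4\Delta/(abc)} with \eqn{a,b,c} the pairwise distances and
#' \eqn{\Delta} the triangle area.  Collinear points have an infinite
#' circumradius and return curvature 0.
#'
#' @param a,b,c Three pairwise-distinct 3D points (numeric length-3 vectors).
#' @return Nonnegative curvature (inverse circumradius).
#' @examples
#' circumcircle_curvature(c(1, 0, 0), c(0, 1, 0), c(-1, 0, 0)) # unit circle
#' @export
circumcircle_curvature <- function(a, b, c) {
  dab <- sqrt(sum((a - b)^2))
  dbc <- sqrt(sum((b - c)^2))
  dac <- sqrt(sum((a - c)^2))
  if (dab == 0 || dbc == 0 || dac == 0) {
    stop_validation("degenerate triangle: coincident points.")
  }
  area2 <- sqrt(sum(cross3(b - a, c - a)^2)) # = 2 * triangle area
  2 * area2 / (dab * dbc * dac)
}

#' Torsion from the normals of successive sample triangles
#'
#' Estimates the (unsigned) torsion at the middle point `c` of five
#' successive samples as the angle between the planes of triangles
#' `(a, b, c)` and `(c, d, e)` divided by the distance between `b` and `d`.
#' The angle is measured between undirected planes (the absolute dot product
#' of the unit normals), so exactly planar curves -- including ones with
#' curvature inflections, where the normals flip sign -- give torsion 0.
#'
#' @param a,b,c,d,e Five successive 3D points.
#' @return Nonnegative torsion estimate; 0 (with a warning) if either
#'   triangle is degenerate (a straight section of the curve).
#' @examples
#' th <- seq(0, 1, length.out = 5)
#' h <- cbind(cos(th), sin(th), 0.5 * th)
#' triangle_normal_torsion(h[1, ], h[2, ], h[3, ], h[4, ], h[5, ])
#' @export
triangle_normal_torsion <- function(a, b, c, d, e) {
  n1 <- cross3(b - a, c - a)
  n2 <- cross3(d - c, e - c)
  l1 <- sqrt(sum(n1^2))
  l2 <- sqrt(sum(n2^2))
  # relative collinearity floor: a triangle whose height is below ~1e-12 of
  # its side lengths has a numerically meaningless normal
  f1 <- sqrt(sum((b - a)^2) * sum((c - a)^2))
  f2 <- sqrt(sum((d - c)^2) * sum((e - c)^2))
  if (l1 <= 1e-12 * f1 || l2 <= 1e-12 * f2) {
    warn("degenerate triangle in torsion estimate (straight section); returning 0.",
         class = "kinprims_degenerate_triangle")
    return(0)
  }
  dbd <- sqrt(sum((d - b)^2))
  if (dbd == 0) stop_validation("degenerate torsion stencil: coincident points b, d.")
  acos(min(1, abs(sum(n1 * n2)) / (l1 * l2))) / dbd
}

profile_checks <- function(curve, min_n) {
  p <- as_curve_matrix(curve)
  if (nrow(p) < min_n) {
    stop_validation(sprintf("curve needs at least %d points.", min_n))
  }
  seg <- rowSums((p[-1L, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2)
  if (any(seg == 0)) stop_validation("degenerate curve: consecutive points coincide.")
  p
}

#' Curvature profile of a backbone curve
#'
#' Applies [circumcircle_curvature()] in a sliding window over the samples.
#' The two endpoint values, where the three-point stencil is undefined, are
#' replicated from the nearest interior value so the profile keeps length
#' `n`.
#'
#' @param curve Curve matrix or data frame with at least 7 points.
#' @return Numeric vector of length `nrow(curve)` of nonnegative curvatures.
#' @export
curvature_profile <- function(curve) {
  p <- profile_checks(curve, 7L)
  n <- nrow(p)
  k <- vapply(2:(n - 1L), function(i) {
    circumcircle_curvature(p[i - 1L, ], p[i, ], p[i + 1L, ])
  }, numeric(1))
  c(k[1L], k, k[n - 2L])
}

#' Torsion profile of a backbone curve
#'
#' Applies [triangle_normal_torsion()] in a sliding five-point window.  The
#' first and last two values, where the stencil is undefined, are replicated
#' from the nearest interior value.  Degenerate (collinear) triangles within
#' straight sections contribute 0 with a single summarizing warning.
#'
#' @inheritParams curvature_profile
#' @return Numeric vector of length `nrow(curve)` of nonnegative torsions.
#' @export
torsion_profile <- function(curve) {
  p <- profile_checks(curve, 7L)
  n <- nrow(p)
  n_degenerate <- 0L
  tau <- vapply(3:(n - 2L), function(i) {
    withCallingHandlers(
      triangle_normal_torsion(p[i - 2L, ], p[i - 1L, ], p[i, ],
                              p[i + 1L, ], p[i + 2L, ]),
      kinprims_degenerate_triangle = function(w) {
        n_degenerate <<- n_degenerate + 1L
        invokeRestart("muffleWarning")
      }
    )
  }, numeric(1))
  if (n_degenerate > 0L) {
    warn(sprintf(
      "%d degenerate torsion stencil(s) (straight sections) set to 0.",
      n_degenerate
    ))
  }
  c(tau[1L], tau[1L], tau, tau[n - 4L], tau[n - 4L])
}

#' Bend-point location of a curve
#'
#' The bend point is the arm-index location (normalized arclength in
#' `[0, 1]`) of maximal curvature.  Flat curves, whose curvature never
#' exceeds `floor`, have no bend.  Ties are broken toward the most proximal
#' (smallest arm index) maximum, deterministically.
#'
#' @param curve Curve matrix or data frame; it is uniformly resampled first
#'   so that sample index is proportional to arclength.
#' @param n Number of resampling points used to locate the maximum.
#' @param floor Minimal curvature for a bend to be declared.
#' @return Arm index of the curvature maximum, in `[0, 1]`.
#' @export
bend_point <- function(curve, n = 100L, floor = 1e-3) {
  p <- resample_uniform(curve, n = n)
  k <- curvature_profile(p)
  if (max(k) <= floor) {
    stop_validation("no bend: curvature profile never exceeds the floor.",
                    class = "kinprims_no_bend")
  }
  (which.max(k) - 1L) / (length(k) - 1L)
}

#' Proximal-length ratio of each frame of a movement
#'
#' For each frame, the ratio between the arclength from the base to the bend
#' point and the total arm length.  Tracked over an extension movement this
#' ratio grows as the proximal section (base to travelling bend) elongates.
#' Operates on unnormalized curves; the ratio itself is scale-free.
#'
#' @param curves Movement table (see [as_movement_tbl()]).
#' @param n Resampling resolution per frame.
#' @param floor Curvature floor passed to [bend_point()].
#' @return Tibble with columns `movement_id`, `frame_index`, `time`, `ratio`.
#' @export
elongation_ratio <- function(curves, n = 100L, floor = 1e-3) {
  mv <- movement_frames(curves)
  purrr::imap_dfr(mv, function(seq, id) {
    ratios <- purrr::imap_dbl(seq$curves, function(p, fi) {
      tryCatch(bend_point(p, n = n, floor = floor),
               kinprims_no_bend = function(e) {
                 stop_validation(sprintf(
                   "movement '%s', frame %s: no bend (flat curvature profile).",
                   id, fi))
               })
    })
    tibble(movement_id = id,
           frame_index = as.integer(names(seq$curves)),
           time = seq$times,
           ratio = unname(ratios))
  })
}
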