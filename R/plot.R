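# ggplot2 views of the pipeline's result types.

#' Heat-map of a kinematic surface
#'
#' @param object A [kin_surface].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.kin_surface <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(.data$s, .data$t,
                                             fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = object$quantity) +
    ggplot2::labs(x = "arm index (base → tip)", y = "normalized time") +
    ggplot2::coord_fixed()
}

# One-sd ellipse outline of each unit on the (s, t) plane.
unit_ellipses <- function(units, n_seg = 60L) {
  purrr::map_dfr(seq_len(nrow(units)), function(i) {
    S <- matrix(c(units$sigma_ss[i], units$sigma_st[i],
                  units$sigma_st[i], units$sigma_tt[i]), 2)
    e <- eigen(S, symmetric = TRUE)
    a <- seq(0, 2 * pi, length.out = n_seg)
    pts <- t(e$vectors %*% rbind(sqrt(e$values[1]) * cos(a),
                                 sqrt(e$values[2]) * sin(a)))
    tibble(unit_id = i, s = pts[, 1] + units$mu_s[i],
           t = pts[, 2] + units$mu_t[i])
  })
}

#' Reconstructed surface with the fitted Gaussian units overlaid
#'
#' @param object A `kin_decomposition`.
#' @param n Grid resolution of the rendered mixture.
#' @param ... Unused.
#' @return A ggplot: mixture heat-map, unit centers and one-sd ellipses.
#' @export
autoplot.kin_decomposition <- function(object, n = 100L, ...) {
  if (nrow(object$units) == 0L) {
    stop_validation("empty decomposition has nothing to plot.")
  }
  p <- autoplot(evaluate_mixture(object$units, n = n,
                                 quantity = object$quantity))
  ell <- unit_ellipses(object$units)
  p +
    ggplot2::geom_path(data = ell,
                       ggplot2::aes(.data$s, .data$t, group = .data$unit_id),
                       inherit.aes = FALSE, color = "white", linewidth = 0.3) +
    ggplot2::geom_point(data = tibble(s = object$units$mu_s,
                                      t = object$units$mu_t),
                        ggplot2::aes(.data$s, .data$t),
                        inherit.aes = FALSE, color = "white", size = 1)
}

#' Gap curve over candidate cluster counts
#'
#' @param object A `kin_gap`.
#' @param ... Unused.
#' @return A ggplot of `Gap(k)` with the selected `k_star` highlighted.
#' @export
autoplot.kin_gap <- function(object, ...) {
  tb <- object$table
  ggplot2::ggplot(tb, ggplot2::aes(.data$k, .data$gap)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_point(data = tb[tb$k == object$k_star, ],
                        color = "red", size = 3) +
    ggplot2::scale_x_continuous(breaks = tb$k) +
    ggplot2::labs(x = "number of clusters k", y = "Gap(k)")
}

#' Unit clusters on the (arm index, time) center plane
#'
#' @param object A `kin_clustering`.
#' @param units The unit table that was clustered (for member positions);
#'   when omitted only the centroids are drawn.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.kin_clustering <- function(object, units = NULL, ...) {
  p <- ggplot2::ggplot()
  if (!is.null(units)) {
    feats <- unit_features(validate_units(units))
    feats$cluster <- factor(object$assignments)
    p <- p + ggplot2::geom_point(
      data = feats,
      ggplot2::aes(.data$center_s, .data$center_t, color = .data$cluster,
                   size = .data$weight),
      alpha = 0.7
    )
  }
  cen <- object$centroids
  p +
    ggplot2::geom_point(data = cen,
                        ggplot2::aes(.data$mu_s, .data$mu_t),
                        shape = 4, size = 4, stroke = 1.5) +
    ggplot2::coord_fixed(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "arm index (base → tip)", y = "normalized time")
}

#' Planar projections of a movement's backbone curves
#'
#' @param curves Movement table (see [as_movement_tbl()]).
#' @param every Draw every `every`-th frame.
#' @return A ggplot: x-y and x-z projections, frames colored by time.
#' @export
plot_movement <- function(curves, every = 1L) {
  curves <- as_movement_tbl(curves)
  frames <- sort(unique(curves$frame_index))
  keep <- frames[seq(1L, length(frames), by = every)]
  df <- curves[curves$frame_index %in% keep, ]
  long <- dplyr::bind_rows(
    dplyr::transmute(df, .data$movement_id, .data$frame_index,
                     h = .data$x, v = .data$y, projection = "x-y"),
    dplyr::transmute(df, .data$movement_id, .data$frame_index,
                     h = .data$x, v = .data$z, projection = "x-z")
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$h, .data$v,
                                     group = .data$frame_index,
                                     color = .data$frame_index)) +
    ggplot2::geom_path(linewidth = 0.3) +
    ggplot2::facet_grid(ggplot2::vars(.data$projection),
                        ggplot2::vars(.data$movement_id)) +
    ggplot2::scale_color_viridis_c(name = "frame") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL)
}
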