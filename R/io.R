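# File formats.
#
# Curve-sequence file: delimited text with header movement_id, frame_index,
# point_index, x, y, z; point_index ascending base to tip.
# Surface file: plain numeric matrix (rows = time grid, columns = arm-index
# grid) as tab-separated text, plus a sidecar JSON "<path>.json" with the
# quantity, grid axes and provenance.
# Decompositions and vocabularies: JSON records.

#' Read and write curve-sequence files
#'
#' @param path File path.
#' @return `read_movements()` returns a validated movement tibble.
#' @export
read_movements <- function(path) {
  curves <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  as_movement_tbl(curves)
}

#' @rdname read_movements
#' @param curves Movement table (see [as_movement_tbl()]).
#' @export
write_movements <- function(curves, path) {
  readr::write_csv(as_movement_tbl(curves), path, progress = FALSE)
  invisible(path)
}

#' Read and write surface files
#'
#' The value matrix is written as headerless tab-separated text; the grid
#' axes, quantity and provenance go to a `"<path>.json"` sidecar.
#'
#' @param surface A [kin_surface].
#' @param path File path of the matrix file.
#' @return `read_surface()` returns a [kin_surface].
#' @export
write_surface <- function(surface, path) {
  stopifnot(inherits(surface, "kin_surface"))
  utils::write.table(surface$values, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  jsonlite::write_json(
    list(quantity = surface$quantity, s_axis = surface$s_axis,
         t_axis = surface$t_axis,
         provenance = list(package = "kinprims",
                           version = as.character(utils::packageVersion("kinprims")))),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_surface
#' @export
read_surface <- function(path) {
  values <- as.matrix(utils::read.table(path, sep = "\t"))
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    kin_surface(values, quantity = meta$quantity, s_axis = meta$s_axis,
                t_axis = meta$t_axis)
  } else {
    kin_surface(values)
  }
}

units_to_record <- function(units) {
  feats <- unit_features(units)
  lapply(seq_len(nrow(units)), function(i) {
    list(
      w = units$w[i],
      mu = c(units$mu_s[i], units$mu_t[i]),
      Sigma = c(units$sigma_ss[i], units$sigma_st[i],
                units$sigma_st[i], units$sigma_tt[i]), # row-major 2 x 2
      features = as.list(feats[i, c("center_s", "center_t", "shape", "size",
                                    "orientation", "weight")])
    )
  })
}

record_to_units <- function(records) {
  purrr::map_dfr(records, function(u) {
    tibble(w = u$w[[1]], mu_s = u$mu[[1]], mu_t = u$mu[[2]],
           sigma_ss = u$Sigma[[1]], sigma_st = u$Sigma[[2]],
           sigma_tt = u$Sigma[[4]])
  })
}

#' Read and write surface-decomposition records
#'
#' JSON with one record per Gaussian unit (`w`, `mu`, row-major `Sigma`,
#' derived features) plus the model summary (`k`, `bic`, `log_likelihood`,
#' `rmse`, `seed`).
#'
#' @param decomposition A `kin_decomposition`.
#' @param path File path.
#' @export
write_decomposition <- function(decomposition, path) {
  stopifnot(inherits(decomposition, "kin_decomposition"))
  jsonlite::write_json(
    list(
      units = units_to_record(decomposition$units),
      k = decomposition$k,
      bic = decomposition$bic,
      log_likelihood = decomposition$log_lik,
      rmse = decomposition$rmse,
      n_obs = decomposition$n_obs,
      total_mass = decomposition$total_mass,
      quantity = decomposition$quantity,
      seed = decomposition$seed
    ),
    path, auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(path)
}

#' @rdname write_decomposition
#' @export
read_decomposition <- function(path) {
  rec <- jsonlite::read_json(path)
  units <- record_to_units(rec$units)
  new_decomposition(validate_units(units), k = rec$k %||% nrow(units),
                    log_lik = rec$log_likelihood %||% NA_real_,
                    bic = rec$bic %||% NA_real_,
                    n_obs = rec$n_obs %||% NA_integer_,
                    total_mass = rec$total_mass %||% sum(units$w),
                    rmse = rec$rmse %||% NA_real_,
                    quantity = rec$quantity %||% "curvature",
                    seed = rec$seed %||% NA_integer_)
}

#' Read and write a kinematic-unit vocabulary
#'
#' The vocabulary file holds the centroid units with their features and
#' cluster sizes, plus a gap-statistic summary when available.
#'
#' @param clustering A `kin_clustering` (or a centroid unit table).
#' @param path File path.
#' @export
write_vocabulary <- function(clustering, path) {
  if (inherits(clustering, "kin_clustering")) {
    centroids <- clustering$centroids
    gap <- clustering$gap
    extras <- list(k = clustering$k,
                   within_dispersion = clustering$within_dispersion,
                   features = clustering$config$features)
  } else {
    centroids <- validate_units(clustering)
    gap <- NULL
    extras <- list(k = nrow(centroids))
  }
  unit_cols <- c("w", "mu_s", "mu_t", "sigma_ss", "sigma_st", "sigma_tt")
  payload <- c(
    list(units = units_to_record(centroids[unit_cols]),
         sizes = if ("n_members" %in% names(centroids)) centroids$n_members),
    extras,
    if (!is.null(gap)) list(gap = list(k_star = gap$k_star, B = gap$B,
                                       k = gap$table$k, W = gap$table$W,
                                       gap = gap$table$gap))
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_vocabulary
#' @export
read_vocabulary <- function(path) {
  rec <- jsonlite::read_json(path)
  validate_units(record_to_units(rec$units))
}

#' Write a movement-classification report
#'
#' JSON with the per-movement weights and residuals, sub-group labels, and
#' prototype weight patterns.
#'
#' @param prototypes A `kin_prototypes`.
#' @param encodings The encoding tibble the prototypes were fitted to.
#' @param path File path.
#' @export
write_classification <- function(prototypes, encodings, path) {
  stopifnot(inherits(prototypes, "kin_prototypes"))
  jsonlite::write_json(
    list(
      movements = lapply(seq_len(nrow(encodings)), function(i) {
        list(movement_id = encodings$movement_id[i],
             weights = as.numeric(encoding_matrix(encodings[i, ])),
             prototype = prototypes$assignments$prototype[i],
             residual_curvature = encodings$residual_curvature[i],
             residual_torsion = encodings$residual_torsion[i])
      }),
      prototype_weights = apply(prototypes$prototype_weights, 1L, as.numeric,
                                simplify = FALSE),
      k = prototypes$k
    ),
    path, auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(path)
}
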