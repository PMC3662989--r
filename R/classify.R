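# Movement classification: encode every movement as a weight vector over a
# shared vocabulary of centroid Gaussians (nonnegative least squares with
# the centroid shapes frozen) and cluster the weight vectors into movement
# prototypes.

vocab_units <- function(vocabulary) {
  if (inherits(vocabulary, "kin_clustering")) {
    vocabulary <- vocabulary$centroids
  }
  validate_units(vocabulary)
}

# NNLS of one surface on the fixed centroid Gaussian basis functions.
encode_surface <- function(surface, vocabulary) {
  units <- vocab_units(vocabulary)
  if (nrow(units) == 0L) stop_validation("empty vocabulary.")
  n_s <- length(surface$s_axis)
  n_t <- length(surface$t_axis)
  grid_s <- rep(surface$s_axis, each = n_t)
  grid_t <- rep(surface$t_axis, times = n_s)
  G <- unit_density(units, grid_s, grid_t)
  b <- as.vector(surface$values)
  if (all(b == 0)) {
    return(list(weights = rep(0, nrow(units)), rmse = 0))
  }
  fit <- pracma::lsqnonneg(G, b)
  list(weights = as.vector(fit$x),
       rmse = sqrt(mean((G %*% fit$x - b)^2)))
}

#' Encode one movement over a shared unit vocabulary
#'
#' Refits the weights of the shared curvature and torsion centroid units to
#' this movement's surfaces by nonnegative least squares, with the units'
#' means and covariances frozen.  The movement is then the weight vector
#' `[{w_i^C}, {w_j^T}]` over curvature units followed by torsion units.
#'
#' With `mode = "pool"`, weights are instead obtained by assigning each of
#' the movement's own fitted Gaussians to its nearest centroid (in the
#' clustering's feature metric) and summing their weights: a coarser
#' encoding provided for comparison.
#'
#' @param surfaces Pair of surfaces: a list with elements `curvature` and
#'   `torsion` ([kin_surface] objects).
#' @param vocab_curvature,vocab_torsion Centroid unit tables (or
#'   `kin_clustering` objects) for curvature and torsion.
#' @param mode `"refit"` (default) or `"pool"`.
#' @param own_units For `mode = "pool"`: this movement's own fitted units,
#'   tagged by `quantity`.
#' @return List with `weights` (named nonnegative vector), `residual_curvature`,
#'   `residual_torsion` (fit rmse per surface; `NA` for `"pool"`).
#' @export
encode_movement <- function(surfaces, vocab_curvature, vocab_torsion,
                            mode = c("refit", "pool"), own_units = NULL) {
  mode <- match.arg(mode)
  vc <- vocab_units(vocab_curvature)
  vt <- vocab_units(vocab_torsion)
  nm <- c(paste0("w_curv_", seq_len(nrow(vc))),
          paste0("w_tors_", seq_len(nrow(vt))))
  if (mode == "refit") {
    ec <- encode_surface(surfaces$curvature, vc)
    et <- encode_surface(surfaces$torsion, vt)
    list(weights = setNames(c(ec$weights, et$weights), nm),
         residual_curvature = ec$rmse, residual_torsion = et$rmse)
  } else {
    if (is.null(own_units)) {
      stop_validation("`mode = \"pool\"` needs the movement's own units.")
    }
    pool_one <- function(vocab, own) {
      w <- rep(0, nrow(vocab))
      if (nrow(own) == 0L) return(w)
      feats_v <- unit_features(vocab)
      feats_o <- unit_features(own)
      config <- compute_feature_scales(
        dplyr::bind_rows(feats_o[names(feats_v)], feats_v), feature_config())
      fm_all <- feature_matrix(
        dplyr::bind_rows(feats_o[c("center_s", "center_t", "shape", "size",
                                   "orientation", "weight")],
                         feats_v[c("center_s", "center_t", "shape", "size",
                                   "orientation", "weight")]), config)
      no <- nrow(feats_o)
      d <- point_centroid_dist(fm_all$mat[seq_len(no), , drop = FALSE],
                               fm_all$mat[no + seq_len(nrow(vocab)), , drop = FALSE],
                               fm_all$groups)
      nearest <- max.col(-d, ties.method = "first")
      for (i in seq_len(no)) w[nearest[i]] <- w[nearest[i]] + own$w[i]
      w
    }
    wc <- pool_one(vc, own_units[own_units$quantity == "curvature", ])
    wt <- pool_one(vt, own_units[own_units$quantity == "torsion", ])
    list(weights = setNames(c(wc, wt), nm),
         residual_curvature = NA_real_, residual_torsion = NA_real_)
  }
}

#' Encode every movement of a surface table
#'
#' @param surfaces Surface tibble from [build_surfaces()].
#' @inheritParams encode_movement
#' @return Tibble with one row per movement: `movement_id`, one nonnegative
#'   weight column per vocabulary unit (`w_curv_*`, then `w_tors_*`), and
#'   the per-surface fit residuals.
#' @export
encode_movements <- function(surfaces, vocab_curvature, vocab_torsion,
                             mode = c("refit", "pool"), units = NULL) {
  mode <- match.arg(mode)
  ids <- unique(surfaces$movement_id)
  purrr::map_dfr(ids, function(id) {
    own <- if (!is.null(units)) units[units$movement_id == id, ] else NULL
    enc <- encode_movement(surface_pair(surfaces, id), vocab_curvature,
                           vocab_torsion, mode = mode, own_units = own)
    dplyr::bind_cols(
      tibble(movement_id = id),
      as_tibble(as.list(enc$weights)),
      tibble(residual_curvature = enc$residual_curvature,
             residual_torsion = enc$residual_torsion)
    )
  })
}

encoding_matrix <- function(encodings) {
  wcols <- grep("^w_(curv|tors)_", names(encodings), value = TRUE)
  if (length(wcols) == 0L) stop_validation("no weight columns in encodings.")
  m <- as.matrix(encodings[wcols])
  rownames(m) <- encodings$movement_id
  m
}

# Gap statistic for plain-Euclidean k-means on the rows of X.
gap_statistic_matrix <- function(X, k_range = 1:6, B = 50L, seed = 1L,
                                 n_init = 10L) {
  withr::local_seed(seed)
  n <- nrow(X)
  lo <- apply(X, 2L, min)
  hi <- apply(X, 2L, max)
  fit_W <- function(M, k) {
    if (k == 1L) {
      sum(scale(M, scale = FALSE)^2)
    } else {
      kmeans(M, centers = k, nstart = n_init, iter.max = 100L)$tot.withinss
    }
  }
  W_k <- vapply(k_range, function(k) fit_W(X, k), numeric(1))
  ref_W <- matrix(NA_real_, B, length(k_range))
  for (b in seq_len(B)) {
    ref <- vapply(seq_along(lo), function(j) runif(n, lo[j], hi[j]), numeric(n))
    ref_W[b, ] <- vapply(k_range, function(k) fit_W(ref, k), numeric(1))
  }
  eps <- 1e-300
  gap <- colMeans(log(pmax(ref_W, eps))) - log(pmax(W_k, eps))
  structure(
    list(table = tibble(k = k_range, W = W_k, gap = gap),
         reference_W = ref_W, B = B,
         k_star = select_gap_k(k_range, gap), config = NULL),
    class = "kin_gap"
  )
}

#' Cluster movement encodings into prototypes
#'
#' Plain-Euclidean k-means on the weight vectors (the weights share units,
#' so no re-normalization is applied).  When `k` is `NULL` the number of
#' sub-groups is chosen by the gap statistic against uniform reference
#' samples over the per-weight bounding box.  Each cluster mean is a
#' prototype weight pattern; when the vocabularies are supplied the
#' prototype surfaces are rendered via [evaluate_mixture()].
#'
#' @param encodings Tibble from [encode_movements()].
#' @param k Number of prototypes, or `NULL` for gap-statistic selection.
#' @param k_range,B Gap-statistic controls (see [gap_statistic()]).
#' @param seed Integer seed.
#' @param n_init k-means restarts.
#' @param vocab_curvature,vocab_torsion Optional centroid unit tables used
#'   to render prototype surfaces.
#' @param n Grid resolution of rendered prototype surfaces.
#' @return A `kin_prototypes`: `assignments` tibble (`movement_id`,
#'   `prototype`), `prototype_weights` matrix (one row per prototype),
#'   `prototype_surfaces` (list of curvature/torsion surface pairs, or
#'   `NULL`), the `kin_gap` when used, and `k`.
#' @export
cluster_movements <- function(encodings, k = NULL, k_range = 1:6, B = 50L,
                              seed = 1L, n_init = 10L,
                              vocab_curvature = NULL, vocab_torsion = NULL,
                              n = 100L) {
  X <- encoding_matrix(encodings)
  gap <- NULL
  if (is.null(k)) {
    gap <- gap_statistic_matrix(X, k_range = k_range, B = B, seed = seed,
                                n_init = n_init)
    k <- gap$k_star
  }
  if (nrow(X) < k) stop_validation("fewer movements than prototypes requested.")
  withr::local_seed(seed)
  if (k == 1L) {
    centers <- matrix(colMeans(X), 1L, ncol(X),
                      dimnames = list(NULL, colnames(X)))
    assign <- rep(1L, nrow(X))
  } else if (k == nrow(X)) {
    # one movement per prototype: stats::kmeans needs k < n
    centers <- X
    rownames(centers) <- NULL
    assign <- seq_len(k)
  } else {
    km <- kmeans(X, centers = k, nstart = n_init, iter.max = 100L)
    centers <- km$centers
    assign <- as.integer(km$cluster)
  }
  surfaces <- NULL
  if (!is.null(vocab_curvature) && !is.null(vocab_torsion)) {
    vc <- vocab_units(vocab_curvature)
    vt <- vocab_units(vocab_torsion)
    surfaces <- lapply(seq_len(k), function(j) {
      wc <- centers[j, seq_len(nrow(vc))]
      wt <- centers[j, nrow(vc) + seq_len(nrow(vt))]
      list(
        curvature = evaluate_mixture(dplyr::mutate(vc, w = unname(wc)),
                                     n = n, quantity = "curvature"),
        torsion = evaluate_mixture(dplyr::mutate(vt, w = unname(wt)),
                                   n = n, quantity = "torsion")
      )
    })
  }
  structure(
    list(assignments = tibble(movement_id = encodings$movement_id,
                              prototype = assign),
         prototype_weights = centers,
         prototype_surfaces = surfaces,
         gap = gap, k = k, seed = seed),
    class = "kin_prototypes"
  )
}

#' Match a movement encoding to its nearest prototype
#'
#' @param encoding One-row encoding tibble (or named weight vector).
#' @param prototypes A `kin_prototypes` from [cluster_movements()].
#' @return Integer prototype label; ties break toward the lowest label.
#' @export
match_movement <- function(encoding, prototypes) {
  stopifnot(inherits(prototypes, "kin_prototypes"))
  P <- prototypes$prototype_weights
  if (is.null(P) || nrow(P) == 0L) stop_validation("empty prototype set.")
  w <- if (is.data.frame(encoding)) {
    as.numeric(encoding_matrix(encoding)[1L, ])
  } else {
    as.numeric(encoding)
  }
  if (length(w) != ncol(P)) {
    stop_validation("encoding length does not match the prototype weights.")
  }
  d <- sqrt(rowSums((P - matrix(w, nrow(P), ncol(P), byrow = TRUE))^2))
  which.min(d) # ties -> lowest label
}

#' @export
print.kin_prototypes <- function(x, ...) {
  cat(sprintf("<kin_prototypes: %d prototype(s), %d movement(s)>\n",
              x$k, nrow(x$assignments)))
  invisible(x)
}

#' Tidy a prototype set: per-movement sub-group labels
#' @param x A `kin_prototypes`.
#' @param ... Unused.
#' @export
tidy.kin_prototypes <- function(x, ...) x$assignments

#' One-row summary of a prototype set
#' @param x A `kin_prototypes`.
#' @param ... Unused.
#' @export
glance.kin_prototypes <- function(x, ...) {
  tibble(k = x$k, n_movements = nrow(x$assignments),
         k_star_gap = if (!is.null(x$gap)) x$gap$k_star else NA_integer_)
}
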