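# Clustering Gaussian units into a vocabulary of kinematic units.
#
# Distances between units are computed per parameter family (center, shape,
# size, orientation, weight): a Euclidean distance for the 2D center, an
# absolute difference for the scalar features, each normalized by its
# sample-wide standard deviation; the distance minimized by the k-means
# variant is the unweighted mean of the enabled component distances.

#' Feature configuration for unit clustering
#'
#' Selects which Gaussian features enter the distance and carries the
#' per-feature normalization scales (sample standard deviations).  The
#' default subset `{center, shape, weight}` is the configuration used for
#' the clustering results on extension movements; `{center, shape, size,
#' orientation}` is the alternative full geometric set.
#'
#' @param features Subset of `"center"`, `"shape"`, `"size"`,
#'   `"orientation"`, `"weight"`.
#' @param scales Optional named numeric vector of normalization scales; when
#'   `NULL` they are computed from the unit sample by
#'   [compute_feature_scales()].
#' @return A `kin_feature_config`.
#' @export
feature_config <- function(features = c("center", "shape", "weight"),
                           scales = NULL) {
  allowed <- c("center", "shape", "size", "orientation", "weight")
  features <- unique(match.arg(features, allowed, several.ok = TRUE))
  if (length(features) == 0L) stop_validation("at least one feature must be enabled.")
  structure(list(features = features, scales = scales),
            class = "kin_feature_config")
}

#' Normalization scales of a unit feature sample
#'
#' One scale per enabled feature: the sample standard deviation (for the 2D
#' center, the root-mean-square of the two coordinate standard deviations).
#' Degenerate features with zero spread are dropped from the configuration
#' with a warning.
#'
#' @param feats Feature table from [unit_features()].
#' @param config A [feature_config()].
#' @return The configuration with `scales` filled in.
#' @export
compute_feature_scales <- function(feats, config = feature_config()) {
  scales <- vapply(config$features, function(f) {
    if (f == "center") {
      sqrt((var(feats$center_s) + var(feats$center_t)) / 2)
    } else {
      sd(feats[[f]])
    }
  }, numeric(1))
  scales[is.na(scales)] <- 0
  degenerate <- scales == 0
  if (any(degenerate)) {
    warn(paste0("dropping degenerate feature(s) with zero spread: ",
                paste(config$features[degenerate], collapse = ", ")))
    config$features <- config$features[!degenerate]
    scales <- scales[!degenerate]
    if (length(config$features) == 0L) {
      stop_validation("all enabled features are degenerate.")
    }
  }
  config$scales <- scales
  config
}

feature_columns <- function(feature) {
  switch(feature, center = c("center_s", "center_t"), feature)
}

needs_scales <- function(config) {
  if (is.null(config$scales)) {
    stop_validation(paste0("feature configuration has no normalization scales; ",
                           "call compute_feature_scales() on the unit sample first."))
  }
  config
}

#' Per-feature distances between two units
#'
#' @param u1,u2 One-row feature tables (see [unit_features()]).
#' @param config A [feature_config()] with scales.
#' @return Named nonnegative vector, one entry per enabled feature.
#' @export
component_distances <- function(u1, u2, config) {
  config <- needs_scales(config)
  vapply(seq_along(config$features), function(i) {
    cols <- feature_columns(config$features[i])
    d <- sqrt(sum((as.numeric(u1[1, cols]) - as.numeric(u2[1, cols]))^2))
    d / config$scales[i]
  }, numeric(1)) |>
    setNames(config$features)
}

#' Distance between two units: mean of the component distances
#'
#' @inheritParams component_distances
#' @return Single nonnegative value; a metric on the enabled feature space.
#' @export
unit_distance <- function(u1, u2, config) {
  mean(component_distances(u1, u2, config))
}

# Feature table -> plain matrix whose columns are grouped per feature, each
# column pre-divided by its feature scale.  `groups` maps feature -> columns.
feature_matrix <- function(feats, config) {
  config <- needs_scales(config)
  cols <- list()
  groups <- list()
  at <- 0L
  for (i in seq_along(config$features)) {
    f <- config$features[i]
    cc <- feature_columns(f)
    block <- as.matrix(feats[cc]) / config$scales[i]
    cols[[f]] <- block
    groups[[f]] <- at + seq_len(ncol(block))
    at <- at + ncol(block)
  }
  list(mat = do.call(cbind, cols), groups = groups)
}

# Mean-of-component distances from every row of `mat` to every centroid row.
point_centroid_dist <- function(mat, centroids, groups) {
  n <- nrow(mat)
  k <- nrow(centroids)
  total <- matrix(0, n, k)
  for (g in groups) {
    for (j in seq_len(k)) {
      diff2 <- (mat[, g, drop = FALSE] -
                  matrix(centroids[j, g], n, length(g), byrow = TRUE))^2
      total[, j] <- total[, j] + sqrt(rowSums(diff2))
    }
  }
  total / length(groups)
}

# One k-means run in feature space with the mean-of-component-distances
# objective: batch (Lloyd) phase, then single-point reassignment passes that
# accept any move lowering the summed point-to-centroid distance.  The
# compiled kernel also reports W, the within-cluster sum of *squared*
# distances, which is the dispersion the gap statistic compares.
kmeans_features <- function(feats, k, config, seed = 1L, n_init = 5L) {
  fm <- feature_matrix(feats, config)
  n <- nrow(fm$mat)
  if (n < k) stop_validation("fewer units than clusters requested.")
  group_start <- vapply(fm$groups, function(g) g[1L] - 1L, integer(1))
  group_len <- lengths(fm$groups)
  withr::local_seed(seed)
  best <- NULL
  for (i in seq_len(n_init)) {
    run <- .kmeans_features_cpp(fm$mat, sample.int(n, k),
                                as.integer(group_start), as.integer(group_len))
    if (is.null(best) || run$objective < best$objective) best <- run
  }
  if (best$reseeded > 0L) {
    inform(sprintf("re-seeded %d emptied cluster(s) at the farthest point.",
                   best$reseeded))
  }
  best$groups <- fm$groups
  best$mat <- fm$mat
  best
}

#' Average Gaussian of a set of units
#'
#' The representative ("centroid") Gaussian of a cluster: the element-wise
#' mean of the members' weights, means and covariance matrices.  A convex
#' combination of SPD matrices, so the result is a valid Gaussian.
#'
#' @param members Unit table (at least one row).
#' @return One-row unit table.
#' @export
cluster_centroid_unit <- function(members) {
  members <- validate_units(members)
  if (nrow(members) == 0L) stop_validation("empty member list.")
  gaussian_units(
    w = mean(members$w),
    mu_s = mean(members$mu_s), mu_t = mean(members$mu_t),
    sigma_ss = mean(members$sigma_ss), sigma_tt = mean(members$sigma_tt),
    sigma_st = mean(members$sigma_st)
  )
}

#' Cluster Gaussian units into kinematic units
#'
#' Runs the two-phase k-means variant (batch updates, then single-point
#' reassignment passes) under the mean of per-feature normalized distances,
#' keeping the best of `n_init` seeded starts.  Cluster centroids are mapped
#' back to representative Gaussians by parameter averaging
#' ([cluster_centroid_unit()]) or, with `centroid_mode = "medoid"`, by the
#' member minimizing the summed distance to its cluster.
#'
#' @param units Gaussian unit table (see [gaussian_units()]).
#' @param k Number of clusters.
#' @param config A [feature_config()]; scales are computed from `units` if
#'   absent.
#' @param seed Integer seed.
#' @param n_init Number of seeded starts.
#' @param centroid_mode `"mean"` (default) or `"medoid"`.
#' @return A `kin_clustering`: `assignments` (label per unit), `centroids`
#'   (representative unit table with features and cluster sizes),
#'   `objective` (the minimized sum of point-to-centroid distances),
#'   `within_dispersion` (`W_k`, the within-cluster sum of squared
#'   point-to-centroid distances used by the gap statistic), `k`, `config`.
#' @export
kmeans_units <- function(units, k, config = feature_config(), seed = 1L,
                         n_init = 5L, centroid_mode = c("mean", "medoid")) {
  centroid_mode <- match.arg(centroid_mode)
  units <- validate_units(units)
  feats <- unit_features(units)
  if (is.null(config$scales)) config <- compute_feature_scales(feats, config)
  run <- kmeans_features(feats, k, config, seed = seed, n_init = n_init)
  centroids <- purrr::map_dfr(seq_len(k), function(j) {
    members <- units[run$assign == j, , drop = FALSE]
    if (centroid_mode == "mean") {
      cluster_centroid_unit(members)
    } else {
      idx <- which(run$assign == j)
      d <- point_centroid_dist(run$mat[idx, , drop = FALSE],
                               run$centroids[j, , drop = FALSE], run$groups)
      members[which.min(d), , drop = FALSE]
    }
  })
  centroids <- dplyr::bind_cols(
    tibble(cluster = seq_len(k), n_members = tabulate(run$assign, k)),
    centroids
  )
  structure(
    list(assignments = run$assign, centroids = centroids,
         objective = run$objective, within_dispersion = run$W,
         k = k, config = config, feature_centroids = run$centroids),
    class = "kin_clustering"
  )
}

#' Gap statistic for the number of unit clusters
#'
#' Compares the log within-cluster dispersion `log(W_k)` of the data with
#' its expectation under `B` Monte Carlo reference samples drawn uniformly
#' within the per-feature bounding box of the sample:
#' \deqn{Gap(k) = \frac{1}{B}\sum_b \log(W^*_{kb}) - \log(W_k).}
#' The selected `k_star` is the minimal `k` at a local maximum of the Gap
#' (endpoints compared one-sided).  Normalization scales are frozen from the
#' data sample and reused for the reference sets.
#'
#' @inheritParams kmeans_units
#' @param k_range Candidate cluster counts, starting at 1.
#' @param B Number of reference data sets (>= 10).
#' @param n_init Seeded k-means starts per fit.
#' @return A `kin_gap`: tibble of `k`, `W`, `gap`; `reference_W`
#'   (`B x |k_range|` matrix); selected `k_star`; `B`.
#' @export
gap_statistic <- function(units, k_range = 1:6, config = feature_config(),
                          B = 50L, seed = 1L, n_init = 3L) {
  units <- validate_units(units)
  if (k_range[1] != 1L) stop_validation("`k_range` must start at 1.")
  if (B < 10L) stop_validation("`B` must be at least 10.")
  feats <- unit_features(units)
  if (is.null(config$scales)) config <- compute_feature_scales(feats, config)
  cols <- unlist(lapply(config$features, feature_columns))
  lo <- vapply(cols, function(cc) min(feats[[cc]]), numeric(1))
  hi <- vapply(cols, function(cc) max(feats[[cc]]), numeric(1))
  n <- nrow(feats)

  withr::local_seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, (B + 1L) * length(k_range))
  ref_sets <- lapply(seq_len(B), function(b) {
    ref <- vapply(seq_along(cols), function(j) runif(n, lo[j], hi[j]),
                  numeric(n))
    colnames(ref) <- cols
    as_tibble(ref)
  })

  W_k <- numeric(length(k_range))
  ref_W <- matrix(NA_real_, B, length(k_range))
  si <- 0L
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    si <- si + 1L
    W_k[i] <- kmeans_features(feats, k, config, seed = seeds[si],
                              n_init = n_init)$W
    for (b in seq_len(B)) {
      si <- si + 1L
      ref_W[b, i] <- kmeans_features(ref_sets[[b]], k, config,
                                     seed = seeds[si], n_init = n_init)$W
    }
  }
  eps <- 1e-300 # guard the log for exact-duplicate degeneracies
  gap <- colMeans(log(pmax(ref_W, eps))) - log(pmax(W_k, eps))
  k_star <- select_gap_k(k_range, gap)
  structure(
    list(table = tibble(k = k_range, W = W_k, gap = gap),
         reference_W = ref_W, B = B, k_star = k_star, config = config),
    class = "kin_gap"
  )
}

# Minimal k at a local maximum of the gap curve; endpoints one-sided.
select_gap_k <- function(k_range, gap) {
  n <- length(gap)
  for (i in seq_len(n)) {
    left_ok <- i == 1L || gap[i] >= gap[i - 1L]
    right_ok <- i == n || gap[i] >= gap[i + 1L]
    if (left_ok && right_ok) return(k_range[i])
  }
  k_range[which.max(gap)]
}

#' Derive the kinematic-unit vocabulary from a unit sample
#'
#' Convenience wrapper: computes features and normalization scales, selects
#' the number of clusters by [gap_statistic()] unless `k` is given, and runs
#' [kmeans_units()].  Units of different quantities (curvature vs torsion)
#' should be clustered separately.
#'
#' @inheritParams kmeans_units
#' @inheritParams gap_statistic
#' @param k Number of clusters, or `NULL` to select by the gap statistic.
#' @return A `kin_clustering` with the `kin_gap` attached as `$gap` when the
#'   gap statistic was used.
#' @export
cluster_units <- function(units, k = NULL, config = feature_config(),
                          k_range = 1:6, B = 50L, seed = 1L, n_init = 5L,
                          centroid_mode = c("mean", "medoid")) {
  units <- validate_units(units)
  feats <- unit_features(units)
  if (is.null(config$scales)) config <- compute_feature_scales(feats, config)
  gap <- NULL
  if (is.null(k)) {
    gap <- gap_statistic(units, k_range = k_range, config = config, B = B,
                         seed = seed)
    k <- gap$k_star
  }
  cl <- kmeans_units(units, k = k, config = config, seed = seed,
                     n_init = n_init, centroid_mode = centroid_mode)
  cl$gap <- gap
  cl
}

#' @export
print.kin_clustering <- function(x, ...) {
  cat(sprintf("<kin_clustering: k = %d, W = %.4f, features = {%s}>\n",
              x$k, x$within_dispersion, paste(x$config$features, collapse = ", ")))
  invisible(x)
}

#' Tidy a unit clustering: the centroid units with features and sizes
#' @param x A `kin_clustering`.
#' @param ... Unused.
#' @export
tidy.kin_clustering <- function(x, ...) {
  dplyr::bind_cols(x$centroids,
                   unit_features(x$centroids[, c("w", "mu_s", "mu_t",
                                                 "sigma_ss", "sigma_st",
                                                 "sigma_tt")]))
}

#' One-row summary of a unit clustering
#' @param x A `kin_clustering`.
#' @param ... Unused.
#' @export
glance.kin_clustering <- function(x, ...) {
  tibble(k = x$k, within_dispersion = x$within_dispersion,
         n_units = length(x$assignments),
         features = paste(x$config$features, collapse = ","),
         k_star_gap = if (!is.null(x$gap)) x$gap$k_star else NA_integer_)
}

#' @export
print.kin_gap <- function(x, ...) {
  cat(sprintf("<kin_gap: k_star = %d, B = %d>\n", x$k_star, x$B))
  print(x$table)
  invisible(x)
}

#' Tidy a gap-statistic result: one row per candidate k
#' @param x A `kin_gap`.
#' @param ... Unused.
#' @export
tidy.kin_gap <- function(x, ...) {
  dplyr::mutate(x$table,
                log_W = log(.data$W),
                mean_log_W_ref = colMeans(log(x$reference_W)),
                se_log_W_ref = apply(log(x$reference_W), 2L, sd),
                selected = .data$k == x$k_star)
}

#' One-row summary of a gap-statistic result
#' @param x A `kin_gap`.
#' @param ... Unused.
#' @export
glance.kin_gap <- function(x, ...) {
  tibble(k_star = x$k_star, B = x$B,
         k_min = min(x$table$k), k_max = max(x$table$k))
}
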