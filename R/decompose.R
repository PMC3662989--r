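# Surface decomposition: approximate a kinematic surface by a weighted sum
# of bivariate Gaussians, z(s, t) = sum_i w_i g[mu_i, Sigma_i](s, t), fitted
# by mass-weighted EM with the number of components chosen by BIC.
#
# Gaussian units live in a tibble with one row per unit and columns
# w, mu_s, mu_t, sigma_ss, sigma_st, sigma_tt.

#' Construct a table of Gaussian units
#'
#' A Gaussian unit is a weighted bivariate Gaussian on the (arm index, time)
#' plane: the elementary kinematic primitive.  All arguments are recycled to
#' a common length.
#'
#' @param w Nonnegative weights (surface-mass units).
#' @param mu_s,mu_t Center coordinates in `[0, 1]` (arm index, time).
#' @param sigma_ss,sigma_tt Covariance diagonal entries (> 0).
#' @param sigma_st Covariance off-diagonal entry; the 2 x 2 covariance must
#'   be positive definite.
#' @return Tibble with one row per unit.
#' @examples
#' gaussian_units(w = c(1, 0.5), mu_s = c(0.3, 0.7), mu_t = c(0.2, 0.8),
#'                sigma_ss = 0.01, sigma_tt = 0.02)
#' @export
gaussian_units <- function(w, mu_s, mu_t, sigma_ss, sigma_tt, sigma_st = 0) {
  units <- tibble(w = as.numeric(w), mu_s = as.numeric(mu_s),
                  mu_t = as.numeric(mu_t), sigma_ss = as.numeric(sigma_ss),
                  sigma_st = as.numeric(sigma_st),
                  sigma_tt = as.numeric(sigma_tt))
  validate_units(units)
}

validate_units <- function(units) {
  required <- c("w", "mu_s", "mu_t", "sigma_ss", "sigma_st", "sigma_tt")
  missing <- setdiff(required, names(units))
  if (length(missing)) {
    stop_validation(paste0("unit table lacks column(s): ",
                           paste(missing, collapse = ", ")))
  }
  if (any(units$w < 0)) stop_validation("unit weights must be nonnegative.")
  det <- units$sigma_ss * units$sigma_tt - units$sigma_st^2
  if (any(units$sigma_ss <= 0) || any(units$sigma_tt <= 0) || any(det <= 0)) {
    stop_validation("unit covariances must be symmetric positive definite.")
  }
  as_tibble(units)
}

# Density of each unit's *unweighted* Gaussian at points (s, t): N x k matrix.
unit_density <- function(units, s, t) {
  k <- nrow(units)
  out <- matrix(0, length(s), k)
  for (i in seq_len(k)) {
    det <- units$sigma_ss[i] * units$sigma_tt[i] - units$sigma_st[i]^2
    ds <- s - units$mu_s[i]
    dt <- t - units$mu_t[i]
    q <- (ds^2 * units$sigma_tt[i] - 2 * ds * dt * units$sigma_st[i] +
            dt^2 * units$sigma_ss[i]) / det
    out[, i] <- exp(-0.5 * q) / (2 * pi * sqrt(det))
  }
  out
}

#' Evaluate a Gaussian mixture as a kinematic surface
#'
#' Renders \eqn{z(s,t) = \sum_i w_i\, g[\mu_i, \Sigma_i](s, t)} on a uniform
#' grid.  The grid sum times the cell area approximates \eqn{\sum_i w_i}
#' whenever all Gaussians lie well inside the unit square.
#'
#' @param units Gaussian unit table (see [gaussian_units()]).
#' @param n Grid resolution (both axes).
#' @param quantity Label for the resulting surface.
#' @return A [kin_surface].
#' @export
evaluate_mixture <- function(units, n = 100L, quantity = "curvature") {
  units <- validate_units(units)
  if (nrow(units) == 0L) stop_validation("empty unit list.")
  s_axis <- seq(0, 1, length.out = n)
  t_axis <- seq(0, 1, length.out = n)
  grid_s <- rep(s_axis, each = n)
  grid_t <- rep(t_axis, times = n)
  dens <- unit_density(units, grid_s, grid_t)
  values <- matrix(as.vector(dens %*% units$w), nrow = n) # rows = time
  kin_surface(values, quantity = quantity, s_axis = s_axis, t_axis = t_axis)
}

#' Geometric features of Gaussian units
#'
#' From each unit's covariance eigendecomposition: the ellipse center,
#' shape (eigenvalue ratio, >= 1), size (geometric-mean standard deviation,
#' an ellipse-area proxy), orientation (angle in degrees between the major
#' principal axis and the arm-index axis, folded into `[0, 90]`; isotropic
#' covariances get orientation 0 by convention), and weight.
#'
#' @param units Gaussian unit table.
#' @return Tibble with columns `center_s`, `center_t`, `shape`, `size`,
#'   `orientation`, `weight` (one row per unit), plus any identifier columns
#'   of the input.
#' @export
unit_features <- function(units) {
  units <- validate_units(units)
  a <- units$sigma_ss
  b <- units$sigma_st
  c <- units$sigma_tt
  tr <- a + c
  disc <- sqrt(pmax((a - c)^2 + 4 * b^2, 0))
  l1 <- (tr + disc) / 2
  l2 <- (tr - disc) / 2
  theta <- ifelse(disc < .Machine$double.eps * tr, 0,
                  0.5 * atan2(2 * b, a - c))
  feats <- tibble(
    center_s = units$mu_s,
    center_t = units$mu_t,
    shape = l1 / l2,
    size = sqrt(l1 * l2),
    orientation = abs(theta) * 180 / pi,
    weight = units$w
  )
  id_cols <- setdiff(names(units),
                     c("w", "mu_s", "mu_t", "sigma_ss", "sigma_st", "sigma_tt"))
  dplyr::bind_cols(units[id_cols], feats)
}

# ---- weighted EM ----------------------------------------------------------

# Positive grid cells of a surface as mass-weighted observations.  Cell
# weights are scaled to sum to the number of positive cells so the weighted
# log-likelihood is on the scale of an ordinary n_obs-point likelihood.
surface_observations <- function(surface) {
  v <- pmax(surface$values, 0) # clip numerical-noise negatives
  pos <- which(v > 0)
  n_s <- length(surface$s_axis)
  n_t <- length(surface$t_axis)
  grid_s <- rep(surface$s_axis, each = n_t)
  grid_t <- rep(surface$t_axis, times = n_s)
  mass <- as.vector(v)[pos]
  list(
    s = grid_s[pos], t = grid_t[pos],
    omega = mass * length(pos) / sum(mass),
    n_obs = length(pos),
    total_mass = surface_mass(surface)
  )
}

# 2x2 eigenvalue floor to keep covariances SPD and off single grid cells.
floor_cov <- function(sxx, sxy, syy, floor = 1e-6) {
  tr <- sxx + syy
  disc <- sqrt(max((sxx - syy)^2 + 4 * sxy^2, 0))
  l1 <- (tr + disc) / 2
  l2 <- (tr - disc) / 2
  if (l2 >= floor) return(c(sxx, sxy, syy))
  if (disc == 0) return(c(max(l1, floor), 0, max(l1, floor)))
  # eigenvector for l1
  if (abs(sxy) > 0) v <- c(l1 - syy, sxy) else if (sxx >= syy) v <- c(1, 0) else v <- c(0, 1)
  v <- v / sqrt(sum(v^2))
  l1 <- max(l1, floor)
  l2 <- floor
  c(l1 * v[1]^2 + l2 * v[2]^2,
    (l1 - l2) * v[1] * v[2],
    l1 * v[2]^2 + l2 * v[1]^2)
}

# kmeans++ seeding on mass-weighted resampled points.
seed_means <- function(obs, k) {
  n_sample <- min(1000L, obs$n_obs)
  idx <- sample.int(obs$n_obs, n_sample, replace = TRUE, prob = obs$omega)
  pts <- cbind(obs$s[idx], obs$t[idx])
  centers <- matrix(NA_real_, k, 2)
  centers[1L, ] <- pts[sample.int(n_sample, 1L), ]
  if (k > 1L) {
    d2 <- rowSums((pts - matrix(centers[1L, ], n_sample, 2, byrow = TRUE))^2)
    for (j in 2:k) {
      if (all(d2 == 0)) {
        centers[j, ] <- pts[sample.int(n_sample, 1L), ]
      } else {
        centers[j, ] <- pts[sample.int(n_sample, 1L, prob = d2), ]
      }
      d2 <- pmin(d2, rowSums((pts - matrix(centers[j, ], n_sample, 2,
                                           byrow = TRUE))^2))
    }
  }
  centers
}

new_decomposition <- function(units, k, log_lik, bic, n_obs, total_mass,
                              rmse, quantity, converged = TRUE, n_iter = NA_integer_,
                              seed = NA_integer_, bic_table = NULL) {
  structure(
    list(units = units, k = k, log_lik = log_lik, bic = bic, n_obs = n_obs,
         total_mass = total_mass, rmse = rmse, quantity = quantity,
         converged = converged, n_iter = n_iter, seed = seed,
         bic_table = bic_table),
    class = "kin_decomposition"
  )
}

#' Fit a k-component Gaussian mixture to a kinematic surface
#'
#' Treats each positive grid cell as a mass-weighted observation (weight
#' proportional to the cell value) and runs weighted
#' expectation-maximization for a `k`-component bivariate Gaussian mixture;
#' the fitted mixture proportions are rescaled by the total surface mass
#' `Z` so that [evaluate_mixture()] of the result approximates the surface
#' in value units and the unit weights add up to `Z`.
#'
#' @param surface A [kin_surface] with positive total mass.
#' @param k Number of Gaussians (>= 1).
#' @param seed Integer seed making the k-means++ initialization (and hence
#'   the whole fit) deterministic.
#' @param tol Relative log-likelihood change declaring convergence.
#' @param max_iter Maximum EM iterations.
#' @return A `kin_decomposition`: unit table, `log_lik`, `bic`
#'   (`-2L + (6k - 1) log(n_obs)` with `n_obs` the positive-cell count),
#'   `total_mass`, `rmse` of the reconstruction, and convergence info.
#'   Zero-mass surfaces yield an empty decomposition with a warning.
#' @export
fit_gmm_surface <- function(surface, k, seed = 1L, tol = 1e-8, max_iter = 500L) {
  stopifnot(inherits(surface, "kin_surface"))
  if (k < 1L) stop_validation("`k` must be at least 1.")
  obs <- surface_observations(surface)
  if (obs$n_obs == 0L || obs$total_mass <= 0) {
    warn("zero-mass surface: returning an empty decomposition.")
    return(new_decomposition(gaussian_units(numeric(0), numeric(0), numeric(0),
                                            numeric(0), numeric(0))[0, ],
                             k = 0L, log_lik = NA_real_, bic = NA_real_,
                             n_obs = 0L, total_mass = 0, rmse = 0,
                             quantity = surface$quantity, seed = seed))
  }
  if (k > obs$n_obs) {
    stop_validation("`k` exceeds the number of grid cells with positive mass.")
  }

  withr::local_seed(seed)
  X <- cbind(obs$s, obs$t)
  omega <- obs$omega
  W <- sum(omega)
  mu <- seed_means(obs, k)
  wvar <- c(sum(omega * (X[, 1] - sum(omega * X[, 1]) / W)^2) / W,
            sum(omega * (X[, 2] - sum(omega * X[, 2]) / W)^2) / W)
  covs <- matrix(rep(c(max(wvar[1] / k, 1e-4), 0, max(wvar[2] / k, 1e-4)), k),
                 nrow = k, byrow = TRUE) # columns: ss, st, tt
  pi_k <- rep(1 / k, k)

  log_lik <- -Inf
  converged <- FALSE
  trace <- numeric(max_iter)
  x1 <- X[, 1L]
  x2 <- X[, 2L]
  logdens <- matrix(0, obs$n_obs, k)
  for (iter in seq_len(max_iter)) {
    # E-step (log-sum-exp over components)
    for (j in seq_len(k)) {
      det <- covs[j, 1] * covs[j, 3] - covs[j, 2]^2
      ds <- x1 - mu[j, 1]
      dt <- x2 - mu[j, 2]
      logdens[, j] <- (log(pi_k[j]) - log(2 * pi) - 0.5 * log(det)) -
        (0.5 / det) * (ds * (ds * covs[j, 3] - 2 * dt * covs[j, 2]) +
                         dt * dt * covs[j, 1])
    }
    mx <- logdens[, 1L]
    for (j in seq_len(k)[-1L]) mx <- pmax(mx, logdens[, j])
    r <- exp(logdens - mx)
    rs <- rowSums(r)
    new_log_lik <- sum(omega * (mx + log(rs)))

    # M-step with per-observation weights
    wr <- (r / rs) * omega
    Nk <- pmax(colSums(wr), .Machine$double.xmin)
    pi_k <- Nk / W
    mu <- crossprod(wr, X) / Nk
    for (j in seq_len(k)) {
      ds <- x1 - mu[j, 1]
      dt <- x2 - mu[j, 2]
      wj <- wr[, j]
      covs[j, ] <- floor_cov(sum(wj * ds * ds) / Nk[j],
                             sum(wj * ds * dt) / Nk[j],
                             sum(wj * dt * dt) / Nk[j])
    }

    trace[iter] <- new_log_lik
    if (is.finite(log_lik) &&
        abs(new_log_lik - log_lik) <= tol * abs(log_lik)) {
      log_lik <- new_log_lik
      converged <- TRUE
      break
    }
    log_lik <- new_log_lik
  }
  trace <- trace[seq_len(iter)]

  units <- gaussian_units(w = pi_k * obs$total_mass,
                          mu_s = mu[, 1], mu_t = mu[, 2],
                          sigma_ss = covs[, 1], sigma_tt = covs[, 3],
                          sigma_st = covs[, 2])
  recon <- evaluate_mixture(units, n = length(surface$s_axis),
                            quantity = surface$quantity)
  rmse <- sqrt(mean((recon$values - surface$values)^2))
  dec <- new_decomposition(units, k = k, log_lik = log_lik,
                           bic = -2 * log_lik + (6 * k - 1) * log(obs$n_obs),
                           n_obs = obs$n_obs, total_mass = obs$total_mass,
                           rmse = rmse, quantity = surface$quantity,
                           converged = converged, n_iter = length(trace),
                           seed = seed)
  attr(dec, "log_lik_trace") <- trace
  dec
}

#' Choose the number of Gaussians by BIC
#'
#' For each `k` in `1..k_max`, runs `n_starts` seeded EM fits and keeps the
#' best likelihood; returns the decomposition whose Bayesian Information
#' Criterion `-2L + (6k - 1) log(n_obs)` is minimal (the most parsimonious
#' model), breaking ties toward smaller `k`.
#'
#' @inheritParams fit_gmm_surface
#' @param k_max Largest number of Gaussians considered.
#' @param n_starts Random restarts per `k`.
#' @return The BIC-optimal `kin_decomposition`, with a `bic_table` tibble
#'   (`k`, `log_lik`, `bic`, `rmse`) covering all candidates.
#' @export
select_num_gaussians <- function(surface, k_max = 6L, n_starts = 5L,
                                 seed = 1L, tol = 1e-8, max_iter = 500L) {
  if (k_max < 1L) stop_validation("`k_max` must be at least 1.")
  withr::local_seed(seed)
  fit_seeds <- matrix(sample.int(.Machine$integer.max - 1L, k_max * n_starts),
                      nrow = k_max)
  best_per_k <- vector("list", k_max)
  for (k in seq_len(k_max)) {
    fits <- lapply(seq_len(n_starts), function(s) {
      fit_gmm_surface(surface, k = k, seed = fit_seeds[k, s],
                      tol = tol, max_iter = max_iter)
    })
    ll <- vapply(fits, `[[`, numeric(1), "log_lik")
    best_per_k[[k]] <- fits[[which.max(ll)]]
  }
  bic_table <- tibble(
    k = seq_len(k_max),
    log_lik = vapply(best_per_k, `[[`, numeric(1), "log_lik"),
    bic = vapply(best_per_k, `[[`, numeric(1), "bic"),
    rmse = vapply(best_per_k, `[[`, numeric(1), "rmse")
  )
  best <- best_per_k[[which.min(bic_table$bic)]] # which.min: ties -> smaller k
  best$bic_table <- bic_table
  best$seed <- seed
  best
}

#' Decompose every surface of a surface table
#'
#' Applies [select_num_gaussians()] to each row of the tibble produced by
#' [build_surfaces()] (or [fit_gmm_surface()] when `k` is fixed).
#'
#' @param surfaces Tibble with columns `movement_id`, `quantity`, `surface`.
#' @param k Fixed number of Gaussians, or `NULL` (default) to choose by BIC.
#' @inheritParams select_num_gaussians
#' @return The input tibble with added columns `decomposition` (list of
#'   `kin_decomposition`), `k`, `bic`, `rmse`.
#' @export
decompose_surfaces <- function(surfaces, k = NULL, k_max = 6L, n_starts = 5L,
                               seed = 1L, tol = 1e-8, max_iter = 500L) {
  stopifnot(all(c("movement_id", "quantity", "surface") %in% names(surfaces)))
  withr::local_seed(seed)
  row_seeds <- sample.int(.Machine$integer.max - 1L, nrow(surfaces))
  dec <- purrr::map2(surfaces$surface, row_seeds, function(surf, s) {
    if (is.null(k)) {
      select_num_gaussians(surf, k_max = k_max, n_starts = n_starts, seed = s,
                           tol = tol, max_iter = max_iter)
    } else {
      fit_gmm_surface(surf, k = k, seed = s, tol = tol, max_iter = max_iter)
    }
  })
  dplyr::mutate(surfaces,
                decomposition = dec,
                k = vapply(dec, `[[`, numeric(1), "k"),
                bic = vapply(dec, `[[`, numeric(1), "bic"),
                rmse = vapply(dec, `[[`, numeric(1), "rmse"))
}

#' Pool the Gaussian units of a decomposed surface table
#'
#' @param decomposed Tibble from [decompose_surfaces()].
#' @return Tibble of all units with their features, tagged by `movement_id`
#'   and `quantity`.
#' @export
extract_units <- function(decomposed) {
  stopifnot("decomposition" %in% names(decomposed))
  purrr::pmap_dfr(
    list(decomposed$movement_id, decomposed$quantity, decomposed$decomposition),
    function(id, qty, dec) {
      if (nrow(dec$units) == 0L) return(NULL)
      dplyr::bind_cols(
        tibble(movement_id = id, quantity = qty,
               unit_id = seq_len(nrow(dec$units))),
        dec$units
      )
    }
  )
}

#' @export
print.kin_decomposition <- function(x, ...) {
  cat(sprintf(
    "<kin_decomposition: %s, k = %d, logLik = %.3f, BIC = %.2f, rmse = %.4g>\n",
    x$quantity, x$k, x$log_lik, x$bic, x$rmse))
  invisible(x)
}

#' Tidy a surface decomposition: one row per Gaussian unit with features
#' @param x A `kin_decomposition`.
#' @param ... Unused.
#' @export
tidy.kin_decomposition <- function(x, ...) {
  if (nrow(x$units) == 0L) return(tibble())
  dplyr::bind_cols(tibble(unit_id = seq_len(nrow(x$units))), x$units,
                   unit_features(x$units))
}

#' One-row model summary of a surface decomposition
#' @param x A `kin_decomposition`.
#' @param ... Unused.
#' @export
glance.kin_decomposition <- function(x, ...) {
  tibble(quantity = x$quantity, k = x$k, log_lik = x$log_lik, bic = x$bic,
         n_obs = x$n_obs, total_mass = x$total_mass, rmse = x$rmse,
         converged = x$converged, n_iter = x$n_iter)
}
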