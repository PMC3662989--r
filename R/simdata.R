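# Synthetic-movement generator: movements whose curvature and torsion
# surfaces are sums of planted 2D Gaussians plus optional noise, rendered
# into 3D curve sequences through the Frenet-Serret synthesis.  Every
# pipeline stage can therefore be validated against known ground truth.

#' Generate a kinematic surface from planted units
#'
#' [evaluate_mixture()] plus seeded Gaussian noise, clipped at zero (both
#' quantities are nonnegative).  With `noise_sd = 0` the output equals the
#' mixture exactly.
#'
#' @param units Planted Gaussian unit table.
#' @param n Grid resolution.
#' @param noise_sd Standard deviation of additive Gaussian noise, in surface
#'   value units (use a fraction of the planted peak for relative noise).
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @param quantity Surface label.
#' @return A [kin_surface].
#' @export
sim_surface <- function(units, n = 100L, noise_sd = 0, seed = NULL,
                        quantity = "curvature") {
  clean <- evaluate_mixture(units, n = n, quantity = quantity)
  if (noise_sd < 0) stop_validation("`noise_sd` must be nonnegative.")
  if (noise_sd == 0) return(clean)
  if (!is.null(seed)) withr::local_seed(seed)
  noisy <- clean$values + matrix(rnorm(n * n, sd = noise_sd), n, n)
  kin_surface(pmax(noisy, 0), quantity = quantity,
              s_axis = clean$s_axis, t_axis = clean$t_axis)
}

#' Generate one synthetic movement with ground truth
#'
#' Evaluates the planted curvature and torsion units on an `m x n`
#' (time x arm index) grid, adds optional surface noise, and reconstructs
#' each time slice as a 3D backbone curve of unit length via
#' [frenet_reconstruct()] with a fixed base frame.
#'
#' @param curvature_units Planted curvature unit table.
#' @param torsion_units Planted torsion unit table, or `NULL` for a planar
#'   movement.
#' @param n Points per curve.
#' @param m Number of frames.
#' @param noise_sd Surface noise standard deviation (value units).
#' @param seed Integer seed, or `NULL`.
#' @param movement_id Identifier for the returned movement table.
#' @return List with `curves` (tidy movement table), `truth` (planted units
#'   per quantity and the noiseless `n x n` surfaces), and the noisy `m x n`
#'   surfaces actually rendered.
#' @export
sim_movement <- function(curvature_units, torsion_units = NULL, n = 100L,
                         m = 40L, noise_sd = 0, seed = NULL,
                         movement_id = "sim") {
  if (!is.null(seed)) withr::local_seed(seed)
  surf_grid <- function(units, qty) {
    if (is.null(units)) return(matrix(0, m, n))
    units <- validate_units(units)
    s_axis <- seq(0, 1, length.out = n)
    t_axis <- seq(0, 1, length.out = m)
    dens <- unit_density(units, rep(s_axis, each = m), rep(t_axis, times = n))
    v <- matrix(as.vector(dens %*% units$w), nrow = m)
    if (noise_sd > 0) v <- v + matrix(rnorm(m * n, sd = noise_sd), m, n)
    pmax(v, 0)
  }
  kap <- surf_grid(curvature_units, "curvature")
  tau <- surf_grid(torsion_units, "torsion")
  curves <- lapply(seq_len(m), function(i) {
    frenet_reconstruct(kap[i, ], tau[i, ], length = 1)
  })
  truth <- list(
    curvature_units = curvature_units,
    torsion_units = torsion_units,
    curvature_surface = if (!is.null(curvature_units)) {
      evaluate_mixture(curvature_units, n = n, quantity = "curvature")
    },
    torsion_surface = if (!is.null(torsion_units)) {
      evaluate_mixture(torsion_units, n = n, quantity = "torsion")
    }
  )
  list(
    curves = frames_to_tbl(setNames(curves, seq_len(m)),
                           movement_id = movement_id),
    truth = truth,
    surfaces = list(curvature = kin_surface(kap, "curvature",
                                            t_axis = seq(0, 1, length.out = m)),
                    torsion = kin_surface(tau, "torsion",
                                          t_axis = seq(0, 1, length.out = m)))
  )
}

#' Generate a set of movements from group weight patterns
#'
#' Emulates a movement repertoire built from a shared vocabulary: each group
#' is a weight pattern over the vocabulary units; each movement draws its
#' weights from its group pattern (with optional multiplicative jitter),
#' renders surfaces plus noise, and synthesizes the 3D curve sequence.
#'
#' @param patterns Numeric matrix, one row per group, columns ordered as
#'   curvature units then torsion units of the vocabulary.
#' @param vocab_curvature,vocab_torsion Vocabulary unit tables (their `w`
#'   columns are ignored; the patterns supply the weights).
#' @param movements_per_group Movements generated per pattern.
#' @param noise_sd Surface noise standard deviation (value units).
#' @param weight_jitter Multiplicative log-normal jitter sd on the weights
#'   (0 disables).
#' @param n,m Curve and frame resolution per movement.
#' @param seed Integer seed.
#' @return List with `curves` (all movements in one tidy table) and `truth`
#'   (tibble: `movement_id`, `group`, drawn weights).
#' @export
sim_movement_set <- function(patterns, vocab_curvature, vocab_torsion,
                             movements_per_group = 10L, noise_sd = 0,
                             weight_jitter = 0, n = 100L, m = 40L,
                             seed = 1L) {
  vc <- validate_units(vocab_curvature)
  vt <- validate_units(vocab_torsion)
  patterns <- as.matrix(patterns)
  if (ncol(patterns) != nrow(vc) + nrow(vt)) {
    stop_validation("pattern columns must match the vocabulary size.")
  }
  withr::local_seed(seed)
  all_curves <- list()
  truth <- list()
  idx <- 0L
  for (g in seq_len(nrow(patterns))) {
    for (r in seq_len(movements_per_group)) {
      idx <- idx + 1L
      id <- sprintf("g%d_m%02d", g, r)
      w <- patterns[g, ]
      if (weight_jitter > 0) {
        w <- w * exp(rnorm(length(w), sd = weight_jitter))
      }
      cu <- vc
      cu$w <- w[seq_len(nrow(vc))]
      tu <- vt
      tu$w <- w[nrow(vc) + seq_len(nrow(vt))]
      mv <- sim_movement(cu, tu, n = n, m = m, noise_sd = noise_sd,
                         movement_id = id)
      all_curves[[idx]] <- mv$curves
      truth[[idx]] <- dplyr::bind_cols(
        tibble(movement_id = id, group = g),
        as_tibble(as.list(setNames(w, c(paste0("w_curv_", seq_len(nrow(vc))),
                                        paste0("w_tors_", seq_len(nrow(vt)))))))
      )
    }
  }
  list(curves = dplyr::bind_rows(all_curves), truth = dplyr::bind_rows(truth))
}

#' Default simulated movement repertoire
#'
#' A reference configuration for the generator: three curvature units (a
#' fixed proximal bend plus two travelling bends) and three torsion units,
#' together with three group weight patterns emphasizing different unit
#' combinations -- an extension-like repertoire with three sub-groups.
#'
#' @return List with `vocab_curvature`, `vocab_torsion` (unit tables) and
#'   `patterns` (3 x 6 weight matrix, curvature units then torsion units).
#' @export
sim_default_repertoire <- function() {
  vocab_curvature <- gaussian_units(
    w = c(0.25, 0.30, 0.25),
    mu_s = c(0.15, 0.45, 0.70),
    mu_t = c(0.40, 0.25, 0.65),
    sigma_ss = c(0.004, 0.008, 0.008),
    sigma_tt = c(0.030, 0.008, 0.008),
    sigma_st = c(0, 0.004, 0.004)
  )
  vocab_torsion <- gaussian_units(
    w = c(0.15, 0.20, 0.15),
    mu_s = c(0.25, 0.60, 0.40),
    mu_t = c(0.25, 0.35, 0.75),
    sigma_ss = c(0.006, 0.008, 0.008),
    sigma_tt = c(0.015, 0.010, 0.012),
    sigma_st = 0
  )
  patterns <- rbind(
    c(1.0, 1.2, 0.2, 0.8, 0.3, 0.1),
    c(0.3, 1.5, 0.9, 0.2, 1.0, 0.3),
    c(1.2, 0.3, 1.1, 0.4, 0.3, 1.0)
  )
  list(vocab_curvature = vocab_curvature, vocab_torsion = vocab_torsion,
       patterns = patterns)
}

#' Planted clusters of Gaussian units in feature space
#'
#' Generates `n_clusters` well-separated groups of units for clustering
#' recovery experiments.  Every enabled feature (center, weight, shape) is
#' separated between groups by about 8 within-cluster standard deviations at
#' `spread = 1`, and the within-cluster spread is a comparable fraction of
#' the between-cluster scale in every feature, so the blobs are roughly
#' isotropic after per-feature normalization.
#'
#' @param n_clusters Number of planted groups (1 to 4).
#' @param n_per Units per group.
#' @param seed Integer seed.
#' @param spread Multiplier on the within-cluster standard deviations
#'   (larger = more overlap; separation is about `8 / spread` sigma).
#' @return List with `units` (unit table) and `labels` (planted group per
#'   unit).
#' @export
sim_unit_blobs <- function(n_clusters = 3L, n_per = 20L, seed = 1L,
                           spread = 1) {
  if (n_clusters < 1L || n_clusters > 4L) {
    stop_validation("`n_clusters` must be between 1 and 4.")
  }
  centers_s <- c(0.20, 0.70, 0.40, 0.80)
  centers_t <- c(0.20, 0.30, 0.80, 0.75)
  w_mean <- c(0.30, 0.80, 1.30, 1.80)
  shape_mean <- c(1.5, 3.0, 4.5, 6.0)
  withr::local_seed(seed)
  units <- purrr::map_dfr(seq_len(n_clusters), function(g) {
    q <- pmax(1.01, shape_mean[g] + rnorm(n_per, 0, 0.18 * spread))
    size <- 0.01
    tibble(
      w = pmax(0.01, w_mean[g] + rnorm(n_per, 0, 0.06 * spread)),
      mu_s = centers_s[g] + rnorm(n_per, 0, 0.06 * spread),
      mu_t = centers_t[g] + rnorm(n_per, 0, 0.06 * spread),
      sigma_ss = size * sqrt(q),
      sigma_st = 0,
      sigma_tt = size / sqrt(q)
    )
  })
  list(units = units, labels = rep(seq_len(n_clusters), each = n_per))
}

#' Analytic fixture curves and surfaces
#'
#' Named, deterministic fixtures with known differential geometry: circles
#' of radius 1 and 2 (curvature 1 and 0.5, torsion 0), a circular helix with
#' radius 1 and pitch parameter 0.5 (curvature 0.8, torsion 0.4), a straight
#' line, a planar S-curve, and an "extension-like" surface built from four
#' planted Gaussians (a fixed proximal bend plus a bend travelling tip-ward
#' over time).
#'
#' The list also contains `bending_movement`, a short synthetic movement
#' whose curvature stays bounded well away from zero on the whole arm
#' (`kappa(s, t) = 1 + 0.8 t sin(pi s)`, `tau(s, t) = 0.4 + 0.3 t cos(pi s)`),
#' so every discrete estimator is well conditioned on it: the fixture of
#' choice for exact-invariance checks.
#'
#' @param n Samples per fixture curve.
#' @param m Frames in the `bending_movement` fixture.
#' @return Named list: curve matrices `line`, `circle_r1`, `circle_r2`,
#'   `helix`, `s_curve`; the movement table `bending_movement`; the planted
#'   unit table `extension_units`; and the rendered surface
#'   `extension_surface`.
#' @export
kin_fixtures <- function(n = 100L, m = 8L) {
  th1 <- seq(0, 2 * pi, length.out = n)
  th4 <- seq(0, 4 * pi, length.out = n)
  xs <- seq(0, 1, length.out = n)
  ext_units <- gaussian_units(
    w = c(0.20, 0.30, 0.35, 0.30),
    mu_s = c(0.15, 0.35, 0.55, 0.75),
    mu_t = c(0.40, 0.20, 0.50, 0.80),
    sigma_ss = c(0.004, 0.008, 0.008, 0.008),
    sigma_tt = c(0.030, 0.006, 0.006, 0.006),
    sigma_st = c(0, 0.004, 0.004, 0.004)
  )
  sgrid <- seq(0, 1, length.out = n)
  bending <- lapply(seq_len(m), function(i) {
    t_i <- (i - 1) / (m - 1)
    frenet_reconstruct(1 + 0.8 * t_i * sin(pi * sgrid),
                       0.4 + 0.3 * t_i * cos(pi * sgrid), length = 1)
  })
  list(
    line = cbind(x = xs, y = 0, z = 0),
    bending_movement = frames_to_tbl(setNames(bending, seq_len(m)),
                                     movement_id = "bending"),
    circle_r1 = cbind(x = cos(th1), y = sin(th1), z = 0),
    circle_r2 = cbind(x = 2 * cos(th1), y = 2 * sin(th1), z = 0),
    helix = cbind(x = cos(th4), y = sin(th4), z = 0.5 * th4),
    s_curve = cbind(x = xs, y = 0.2 * sin(2 * pi * xs), z = 0),
    extension_units = ext_units,
    extension_surface = evaluate_mixture(ext_units, n = n,
                                         quantity = "curvature")
  )
}
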