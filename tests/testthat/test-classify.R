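vocab_pair <- function() {
  rep <- sim_default_repertoire()
  list(vc = rep$vocab_curvature, vt = rep$vocab_torsion,
       patterns = rep$patterns)
}

test_that("weights are recovered exactly for surfaces built on the basis", {
  v <- vocab_pair()
  w_true <- c(0.9, 0.2, 1.4, 0.5, 1.1, 0.3)
  cu <- v$vc; cu$w <- w_true[1:3]
  tu <- v$vt; tu$w <- w_true[4:6]
  surfaces <- list(curvature = evaluate_mixture(cu, n = 80),
                   torsion = evaluate_mixture(tu, n = 80, quantity = "torsion"))
  enc <- encode_movement(surfaces, v$vc, v$vt)
  expect_equal(unname(enc$weights), w_true, tolerance = 1e-6)
  expect_lt(enc$residual_curvature, 1e-8)
  expect_lt(enc$residual_torsion, 1e-8)
})

test_that("all-zero surfaces encode to the zero vector and weights stay nonnegative", {
  v <- vocab_pair()
  zero <- list(curvature = kin_surface(matrix(0, 40, 40)),
               torsion = kin_surface(matrix(0, 40, 40), quantity = "torsion"))
  enc <- encode_movement(zero, v$vc, v$vt)
  expect_equal(unname(enc$weights), rep(0, 6))

  # weights nonnegative for arbitrary (noisy) surfaces
  set.seed(8)
  noisy <- list(
    curvature = kin_surface(matrix(abs(rnorm(1600)), 40, 40)),
    torsion = kin_surface(matrix(abs(rnorm(1600)), 40, 40), quantity = "torsion")
  )
  expect_true(all(encode_movement(noisy, v$vc, v$vt)$weights >= 0))
})

test_that("encoding round trip beats the best single-unit fit", {
  v <- vocab_pair()
  cu <- v$vc; cu$w <- v$patterns[2, 1:3]
  surface <- evaluate_mixture(cu, n = 60)
  encode_surface_rmse <- function(vocab) {
    kinprims:::encode_surface(surface, vocab)$rmse
  }
  full <- encode_surface_rmse(v$vc)
  singles <- vapply(1:3, function(i) encode_surface_rmse(v$vc[i, ]), numeric(1))
  expect_lte(full, min(singles))
})

test_that("movement clustering recovers planted weight patterns with gap-selected k", {
  v <- vocab_pair()
  set.seed(9)
  groups <- rep(1:3, each = 10)
  X <- abs(v$patterns[groups, ] + matrix(rnorm(180, 0, 0.08), 30, 6))
  enc <- tibble::as_tibble(as.data.frame(X))
  names(enc) <- c(paste0("w_curv_", 1:3), paste0("w_tors_", 1:3))
  enc <- dplyr::bind_cols(tibble::tibble(movement_id = sprintf("m%02d", 1:30)),
                          enc)
  proto <- cluster_movements(enc, k = NULL, B = 50, seed = 9,
                             vocab_curvature = v$vc, vocab_torsion = v$vt,
                             n = 40)
  expect_equal(proto$k, 3L)
  expect_gte(ari(proto$assignments$prototype, groups), 0.9)
  expect_length(proto$prototype_surfaces, 3L)
  expect_s3_class(proto$prototype_surfaces[[1]]$curvature, "kin_surface")

  # order invariance of the partition
  perm <- sample(30)
  proto2 <- cluster_movements(enc[perm, ], k = 3, seed = 5)
  expect_equal(ari(proto2$assignments$prototype, groups[perm]), 1)
})

test_that("identical encodings collapse to a single prototype equal to the common vector", {
  v <- vocab_pair()
  enc <- dplyr::bind_rows(lapply(1:5, function(i) {
    tibble::tibble(movement_id = paste0("m", i), w_curv_1 = 0.4,
                   w_curv_2 = 1.1, w_tors_1 = 0.7)
  }))
  proto <- cluster_movements(enc, k = 1, seed = 1)
  expect_equal(unname(proto$prototype_weights[1, ]), c(0.4, 1.1, 0.7))
  expect_equal(proto$assignments$prototype, rep(1L, 5))
})

test_that("a noiseless single-movement cluster reproduces its surfaces within residual", {
  v <- vocab_pair()
  cu <- v$vc; cu$w <- v$patterns[1, 1:3]
  tu <- v$vt; tu$w <- v$patterns[1, 4:6]
  surfaces <- list(curvature = evaluate_mixture(cu, n = 60),
                   torsion = evaluate_mixture(tu, n = 60, quantity = "torsion"))
  enc <- encode_movement(surfaces, v$vc, v$vt)
  enc_tbl <- dplyr::bind_cols(tibble::tibble(movement_id = "m1"),
                              tibble::as_tibble(as.list(enc$weights)))
  proto <- cluster_movements(enc_tbl, k = 1, seed = 1, vocab_curvature = v$vc,
                             vocab_torsion = v$vt, n = 60)
  recon <- proto$prototype_surfaces[[1]]$curvature
  rmse <- sqrt(mean((recon$values - surfaces$curvature$values)^2))
  expect_lte(rmse, enc$residual_curvature + 1e-8)
})

test_that("match_movement returns the nearest prototype with deterministic ties", {
  proto <- structure(
    list(prototype_weights = rbind(c(1, 0, 0), c(0, 1, 0)),
         assignments = tibble::tibble(movement_id = c("a", "b"),
                                      prototype = 1:2),
         k = 2L),
    class = "kin_prototypes"
  )
  expect_equal(match_movement(c(1, 0, 0), proto), 1L)
  expect_equal(match_movement(c(0, 0.9, 0), proto), 2L)
  # equidistant encoding: the lower label wins
  expect_equal(match_movement(c(0.5, 0.5, 0), proto), 1L)
  expect_error(match_movement(c(1, 0), proto), class = "kinprims_validation_error")

  # planted-pattern draws are assigned to their generating prototype
  set.seed(10)
  hits <- replicate(100, {
    g <- sample(1:2, 1)
    noisy <- proto$prototype_weights[g, ] + rnorm(3, 0, 0.1)
    match_movement(noisy, proto) == g
  })
  expect_gte(mean(hits), 0.9)
})

test_that("pooled encoding assigns each movement's own Gaussians to nearest centroids", {
  v <- vocab_pair()
  own <- dplyr::bind_cols(
    tibble::tibble(movement_id = "m1",
                   quantity = c("curvature", "curvature", "torsion")),
    dplyr::bind_rows(v$vc[1, ], v$vc[1, ], v$vt[2, ])
  )
  own$w <- c(0.3, 0.4, 0.6)
  surfaces <- list(curvature = kin_surface(matrix(0, 20, 20)),
                   torsion = kin_surface(matrix(0, 20, 20), quantity = "torsion"))
  enc <- encode_movement(surfaces, v$vc, v$vt, mode = "pool", own_units = own)
  expect_equal(unname(enc$weights),
               c(0.7, 0, 0, 0, 0.6, 0))
})
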