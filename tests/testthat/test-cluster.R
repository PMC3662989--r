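units_for_distance <- function() {
  gaussian_units(w = c(0.5, 0.8), mu_s = c(0.2, 0.2), mu_t = c(0.2, 0.5),
                 sigma_ss = c(0.01, 0.02), sigma_tt = c(0.01, 0.01))
}

test_that("component distances are per-feature, normalized and symmetric", {
  feats <- unit_features(units_for_distance())
  config <- feature_config(scales = c(center = 1, shape = 1, weight = 1))
  d12 <- component_distances(feats[1, ], feats[2, ], config)
  expect_named(d12, c("center", "shape", "weight"))
  expect_equal(unname(d12["center"]), 0.3)
  expect_equal(d12, component_distances(feats[2, ], feats[1, ], config))
  expect_equal(unname(component_distances(feats[1, ], feats[1, ], config)),
               rep(0, 3))
  expect_error(unit_distance(feats[1, ], feats[2, ], feature_config()),
               class = "kinprims_validation_error")
})

test_that("unit distance is the mean component distance and a metric", {
  feats <- unit_features(units_for_distance())
  config <- feature_config(scales = c(center = 1, shape = 1, weight = 1))
  expect_equal(unit_distance(feats[1, ], feats[2, ], config),
               mean(component_distances(feats[1, ], feats[2, ], config)))

  # units differing in exactly one feature: mean = component / |enabled|
  u <- gaussian_units(w = c(0.5, 0.9), mu_s = 0.3, mu_t = 0.3,
                      sigma_ss = 0.01, sigma_tt = 0.02)
  f <- unit_features(u)
  expect_equal(unit_distance(f[1, ], f[2, ], config), 0.4 / 3)

  # triangle inequality on random triples
  set.seed(4)
  blobs <- sim_unit_blobs(3, n_per = 30, seed = 4)$units
  feats <- unit_features(blobs)
  config <- compute_feature_scales(feats, feature_config())
  for (i in 1:200) {
    idx <- sample.int(nrow(feats), 3)
    dab <- unit_distance(feats[idx[1], ], feats[idx[2], ], config)
    dbc <- unit_distance(feats[idx[2], ], feats[idx[3], ], config)
    dac <- unit_distance(feats[idx[1], ], feats[idx[3], ], config)
    expect_lte(dac, dab + dbc + 1e-12)
  }
})

test_that("k-means recovers planted feature-space blobs exactly", {
  blobs <- sim_unit_blobs(3, n_per = 20, seed = 1)
  cl <- kmeans_units(blobs$units, k = 3, seed = 1)
  expect_equal(ari(cl$assignments, blobs$labels), 1)
  expect_equal(sort(cl$centroids$n_members), c(20L, 20L, 20L))

  # determinism given the seed
  cl2 <- kmeans_units(blobs$units, k = 3, seed = 1)
  expect_identical(cl$assignments, cl2$assignments)

  # invariance to input order, up to label permutation
  perm <- sample(seq_len(60))
  cl3 <- kmeans_units(blobs$units[perm, ], k = 3, seed = 7)
  expect_equal(ari(cl3$assignments, blobs$labels[perm]), 1)
})

test_that("duplicated distinct units cluster with zero objective", {
  base <- sim_unit_blobs(3, n_per = 1, seed = 2)$units
  dup <- dplyr::bind_rows(base, base, base)
  cl <- kmeans_units(dup, k = 3, seed = 1)
  expect_equal(cl$objective, 0, tolerance = 1e-12)
  expect_equal(unname(table(cl$assignments)), rep(3L, 3), ignore_attr = TRUE)
})

test_that("cluster centroids average the member Gaussians and stay SPD", {
  u <- units_for_distance()
  expect_equal(cluster_centroid_unit(u[1, ]), u[1, ])
  cen <- cluster_centroid_unit(u)
  expect_equal(cen$w, mean(u$w))
  expect_equal(cen$sigma_ss, mean(u$sigma_ss))
  expect_gt(cen$sigma_ss * cen$sigma_tt - cen$sigma_st^2, 0)

  same <- dplyr::bind_rows(u[1, ], u[1, ], u[1, ])
  expect_equal(unit_features(cluster_centroid_unit(same)),
               unit_features(u[1, ]))
})

test_that("gap values recompute from the stored dispersion fields", {
  blobs <- sim_unit_blobs(2, n_per = 15, seed = 3)
  gap <- gap_statistic(blobs$units, k_range = 1:4, B = 12, seed = 3)
  recomputed <- colMeans(log(gap$reference_W)) - log(gap$table$W)
  expect_equal(gap$table$gap, recomputed)
  expect_true(gap$k_star %in% gap$table$k)
  expect_equal(dim(gap$reference_W), c(12L, 4L))
})

test_that("the gap statistic recovers planted cluster counts", {
  for (k_true in c(2, 3)) {
    blobs <- sim_unit_blobs(k_true, n_per = 20, seed = 10 + k_true)
    gap <- gap_statistic(blobs$units, k_range = 1:6, B = 50,
                         seed = 10 + k_true)
    expect_equal(gap$k_star, k_true)
  }
  # a single blob against the uniform reference stays a single cluster
  one <- sim_unit_blobs(1, n_per = 60, seed = 5)
  expect_equal(gap_statistic(one$units, k_range = 1:6, B = 50, seed = 5)$k_star,
               1L)
})

test_that("degenerate features are dropped with a warning", {
  u <- gaussian_units(w = 1, mu_s = runif(10), mu_t = runif(10),
                      sigma_ss = 0.01, sigma_tt = 0.02)
  feats <- unit_features(u)
  expect_warning(config <- compute_feature_scales(feats, feature_config()),
                 "degenerate")
  expect_false("weight" %in% config$features)
})

test_that("cluster_units wires the gap statistic into the vocabulary build", {
  blobs <- sim_unit_blobs(3, n_per = 15, seed = 6)
  cl <- cluster_units(blobs$units, k = NULL, k_range = 1:5, B = 20, seed = 6)
  expect_equal(cl$k, 3L)
  expect_equal(ari(cl$assignments, blobs$labels), 1)
  expect_s3_class(cl$gap, "kin_gap")
  expect_equal(glance(cl)$k_star_gap, 3L)
  expect_equal(nrow(tidy(cl)), 3L)

  med <- kmeans_units(blobs$units, k = 3, seed = 2, centroid_mode = "medoid")
  # each medoid is an actual member unit
  for (i in seq_len(3)) {
    expect_true(any(abs(blobs$units$mu_s - med$centroids$mu_s[i]) < 1e-12))
  }
})
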