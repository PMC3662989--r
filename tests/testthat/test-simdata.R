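test_that("surface generation is exact without noise and reproducible with it", {
  u <- gaussian_units(0.5, 0.4, 0.6, 0.01, 0.02)
  clean <- sim_surface(u, n = 50)
  expect_equal(clean$values, evaluate_mixture(u, n = 50)$values)

  a <- sim_surface(u, n = 50, noise_sd = 0.3, seed = 42)
  b <- sim_surface(u, n = 50, noise_sd = 0.3, seed = 42)
  expect_identical(a$values, b$values)
  expect_gt(max(abs(a$values - clean$values)), 0)
})

test_that("requested noise level is realized in the pre-clipping regime", {
  # a surface with a high floor so clipping never engages
  u <- gaussian_units(w = 50, mu_s = 0.5, mu_t = 0.5,
                      sigma_ss = 0.5, sigma_tt = 0.5)
  clean <- evaluate_mixture(u, n = 80)
  noisy <- sim_surface(u, n = 80, noise_sd = 0.5, seed = 1)
  resid_sd <- sd(noisy$values - clean$values)
  expect_lt(abs(resid_sd - 0.5) / 0.5, 0.1)
})

test_that("generated movements round-trip through surface extraction", {
  units <- roundtrip_units()
  mv <- sim_movement(units$curvature, units$torsion, n = 60, m = 20)
  surf <- build_surfaces(mv$curves, n = 60, tip_exclude = 0)
  for (q in c("curvature", "torsion")) {
    truth <- mv$truth[[paste0(q, "_surface")]]$values
    got <- surf$surface[[match(q, surf$quantity)]]$values
    expect_lt(sqrt(mean((got - truth)^2)) / max(truth), 0.02)
  }
})

test_that("the generator is bit-reproducible given a seed", {
  u <- roundtrip_units()
  a <- sim_movement(u$curvature, u$torsion, n = 30, m = 8, noise_sd = 0.1,
                    seed = 7)
  b <- sim_movement(u$curvature, u$torsion, n = 30, m = 8, noise_sd = 0.1,
                    seed = 7)
  expect_identical(a$curves, b$curves)

  rep <- sim_default_repertoire()
  s1 <- sim_movement_set(rep$patterns[1:2, ], rep$vocab_curvature,
                         rep$vocab_torsion, movements_per_group = 2,
                         n = 30, m = 6, seed = 3)
  s2 <- sim_movement_set(rep$patterns[1:2, ], rep$vocab_curvature,
                         rep$vocab_torsion, movements_per_group = 2,
                         n = 30, m = 6, seed = 3)
  expect_identical(s1$curves, s2$curves)
  expect_equal(dplyr::n_distinct(s1$curves$movement_id), 4L)
})

test_that("fixtures regenerate identically and match their closed forms", {
  f1 <- kin_fixtures()
  f2 <- kin_fixtures()
  expect_identical(f1$helix, f2$helix)
  expect_identical(f1$extension_surface$values, f2$extension_surface$values)

  kap <- curvature_profile(f1$helix)
  expect_lt(max(abs(kap[2:99] - 0.8)) / 0.8, 0.01)
  expect_equal(curvature_profile(f1$line), rep(0, 100))
  expect_equal(suppressWarnings(torsion_profile(f1$line)), rep(0, 100))
  expect_equal(nrow(f1$extension_units), 4L)
})

test_that("planted unit blobs are labeled, separated and seed-stable", {
  b <- sim_unit_blobs(3, n_per = 10, seed = 2)
  expect_equal(nrow(b$units), 30L)
  expect_equal(b$labels, rep(1:3, each = 10))
  expect_identical(b$units, sim_unit_blobs(3, n_per = 10, seed = 2)$units)
  expect_error(sim_unit_blobs(5), class = "kinprims_validation_error")
})
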