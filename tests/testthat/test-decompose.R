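test_that("a single planted Gaussian is recovered by one EM component", {
  truth <- gaussian_units(w = 1, mu_s = 0.5, mu_t = 0.5,
                          sigma_ss = 0.01, sigma_tt = 0.02)
  dec <- fit_gmm_surface(evaluate_mixture(truth, n = 100), k = 1, seed = 3)
  expect_lt(abs(dec$units$mu_s - 0.5), 0.01)
  expect_lt(abs(dec$units$mu_t - 0.5), 0.01)
  expect_lt(abs(dec$units$sigma_ss - 0.01) / 0.01, 0.05)
  expect_lt(abs(dec$units$sigma_tt - 0.02) / 0.02, 0.05)
  expect_lt(abs(dec$units$w - 1), 0.01)
})

test_that("two well-separated planted Gaussians are both located within 0.02", {
  truth <- gaussian_units(w = c(1, 0.8), mu_s = c(0.25, 0.75),
                          mu_t = c(0.25, 0.75), sigma_ss = 0.01,
                          sigma_tt = 0.01)
  dec <- fit_gmm_surface(evaluate_mixture(truth, n = 100), k = 2, seed = 5)
  found <- dec$units[order(dec$units$mu_s), ]
  expect_lt(max(abs(found$mu_s - c(0.25, 0.75))), 0.02)
  expect_lt(max(abs(found$mu_t - c(0.25, 0.75))), 0.02)
})

test_that("the weighted EM log-likelihood never decreases", {
  for (seed in 1:3) {
    dec <- fit_gmm_surface(fixtures$extension_surface, k = 3, seed = seed)
    trace <- attr(dec, "log_lik_trace")
    expect_gt(length(trace), 1L)
    expect_true(all(diff(trace) >= -1e-8 * abs(trace[-length(trace)])))
  }
})

test_that("unit weights conserve the surface mass", {
  for (k in c(1, 3, 5)) {
    dec <- fit_gmm_surface(fixtures$extension_surface, k = k, seed = k)
    expect_equal(sum(dec$units$w), dec$total_mass,
                 tolerance = 1e-6)
  }
})

test_that("BIC recomputes from the stored fields and selects parsimonious models", {
  sel <- select_num_gaussians(fixtures$extension_surface, k_max = 5,
                              n_starts = 2, seed = 2)
  expect_equal(sel$bic, -2 * sel$log_lik + (6 * sel$k - 1) * log(sel$n_obs))
  expect_equal(sel$k, 4) # the fixture plants four Gaussians
  # every multi-component fit reconstructs at least as well as the best
  # single Gaussian (EM optimizes likelihood, so rmse is only guaranteed
  # against the k = 1 baseline)
  expect_true(all(sel$bic_table$rmse <= sel$bic_table$rmse[1] + 1e-9))

  single <- gaussian_units(1, 0.4, 0.6, 0.01, 0.01)
  sel1 <- select_num_gaussians(evaluate_mixture(single, n = 60), k_max = 3,
                               n_starts = 2, seed = 1)
  expect_equal(sel1$k, 1)
})

test_that("degenerate surfaces are rejected or yield empty decompositions", {
  zero <- kin_surface(matrix(0, 20, 20))
  expect_warning(dec <- fit_gmm_surface(zero, k = 2), "zero-mass")
  expect_equal(nrow(dec$units), 0L)
  expect_equal(dec$k, 0L)

  tiny <- kin_surface(matrix(c(rep(0, 98), 1, 1), 10, 10))
  expect_error(fit_gmm_surface(tiny, k = 5),
               class = "kinprims_validation_error")
})

test_that("unit features fold covariance geometry into shape, size and orientation", {
  iso <- gaussian_units(1, 0.5, 0.5, 0.04, 0.04)
  f <- unit_features(iso)
  expect_equal(f$shape, 1)
  expect_equal(f$orientation, 0)

  aligned <- gaussian_units(1, 0.5, 0.5, sigma_ss = 4, sigma_tt = 1)
  f2 <- unit_features(aligned)
  expect_equal(f2$shape, 4)
  expect_equal(f2$orientation, 0)
  expect_equal(f2$size, 2)

  # diag(4, 1) rotated by 45 degrees
  R <- matrix(c(1, 1, -1, 1), 2) / sqrt(2)
  S <- R %*% diag(c(4, 1)) %*% t(R)
  rot <- gaussian_units(1, 0.5, 0.5, sigma_ss = S[1, 1], sigma_tt = S[2, 2],
                        sigma_st = S[1, 2])
  expect_equal(unit_features(rot)$orientation, 45, tolerance = 1e-9)

  expect_error(gaussian_units(1, 0.5, 0.5, sigma_ss = 1, sigma_tt = 1,
                              sigma_st = 2),
               class = "kinprims_validation_error")
})

test_that("evaluate_mixture integrates to the unit weights and decays far away", {
  u <- gaussian_units(1, 0.5, 0.5, 0.005, 0.005)
  surf <- evaluate_mixture(u, n = 100)
  cell <- (1 / 99)^2
  expect_equal(sum(surf$values) * cell, 1, tolerance = 1e-3)
  # cells far outside the support (> 6.5 sigma) are negligible
  far <- tidy(surf)
  far <- far[sqrt((far$s - 0.5)^2 + (far$t - 0.5)^2) > 6.5 * sqrt(0.005), ]
  expect_lt(max(far$value), 1e-8 * max(surf$values))
})

test_that("decompose_surfaces and extract_units operate over the surface table", {
  mv <- sim_movement(gaussian_units(0.4, 0.5, 0.5, 0.01, 0.02), n = 60, m = 10)
  surf <- build_surfaces(mv$curves, n = 60)
  dec <- suppressWarnings(decompose_surfaces(surf, k = 1, seed = 1))
  expect_true(all(c("decomposition", "k", "bic", "rmse") %in% names(dec)))
  units <- extract_units(dec)
  expect_true(all(units$movement_id == "sim"))
  expect_setequal(unique(units$quantity), c("curvature"))
  # the torsion surface of a planar movement is empty -> no torsion units
  expect_equal(glance(dec$decomposition[[1]])$k, 1)
  td <- tidy(dec$decomposition[[1]])
  expect_true(all(c("center_s", "shape", "orientation") %in% names(td)))
})
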