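test_that("uniform resampling spaces points equally and preserves endpoints", {
  seg <- rbind(c(0, 0, 0), c(1, 0, 0))
  out <- resample_uniform(seg, n = 5)
  expect_equal(out[, "x"], c(0, 0.25, 0.5, 0.75, 1))
  expect_equal(out[, "y"], rep(0, 5))

  # idempotence on an already-uniform sampling
  th <- seq(0, pi / 2, length.out = 50)
  arc <- cbind(cos(th), sin(th), 0)
  u1 <- resample_uniform(arc, n = 50)
  expect_equal(max(abs(resample_uniform(u1, n = 50) - u1)), 0,
               tolerance = 1e-9)

  # dense semicircle: adjacent chords equal to 0.1% relative
  th <- seq(0, pi, length.out = 1000)
  semi <- resample_uniform(cbind(cos(th), sin(th), 0), n = 100)
  chords <- sqrt(rowSums(diff(semi)^2))
  expect_lt(diff(range(chords)) / mean(chords), 1e-3)

  expect_error(resample_uniform(rbind(c(1, 2, 3), c(1, 2, 3)), n = 10),
               class = "kinprims_validation_error")
  expect_error(resample_uniform(seg, n = 1), class = "kinprims_validation_error")
})

test_that("circumcircle curvature matches collinear, unit-circle and oracle cases", {
  expect_equal(circumcircle_curvature(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)), 0)
  expect_equal(circumcircle_curvature(c(1, 0, 0), c(0, 1, 0), c(-1, 0, 0)), 1,
               tolerance = 1e-12)
  # circumcenter of (0,0), (1,1), (2,0) is (1,0) with radius 1
  expect_equal(circumcircle_curvature(c(0, 0, 0), c(1, 1, 0), c(2, 0, 0)), 1,
               tolerance = 1e-12)
  expect_error(circumcircle_curvature(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0)),
               class = "kinprims_validation_error")
})

test_that("triangle-normal torsion matches coplanar, perpendicular and helix oracles", {
  # coplanar points: parallel normals, zero torsion
  flat <- cbind(seq(0, 2, length.out = 5), c(0, 1, 0.5, 1.2, 0.3), 0)
  expect_equal(triangle_normal_torsion(flat[1, ], flat[2, ], flat[3, ],
                                       flat[4, ], flat[5, ]), 0)

  # orthogonal plane normals (z vs x) with d(B, D) = 2: arccos(0) / 2 = pi / 4
  a <- c(-1, 1, 0); b <- c(0, -1, 0); c_ <- c(0, 0, 0)
  d <- c(0, 1, 0); e <- c(0, 0, 1)
  expect_equal(triangle_normal_torsion(a, b, c_, d, e), pi / 4,
               tolerance = 1e-12)

  # dense helix: closed form tau = b / (a^2 + b^2) = 0.4
  tau <- torsion_profile(fixtures$helix)
  expect_lt(max(abs(tau[3:98] - 0.4)) / 0.4, 0.01)

  expect_warning(
    triangle_normal_torsion(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0),
                            c(3, 1, 0), c(4, 0, 1)),
    class = "kinprims_degenerate_triangle")
})

test_that("curvature and torsion profiles recover circle and helix closed forms", {
  kap2 <- curvature_profile(fixtures$circle_r2)
  expect_lt(max(abs(kap2[2:99] - 0.5)) / 0.5, 0.01)
  expect_length(kap2, 100)

  kap_h <- curvature_profile(fixtures$helix)
  expect_lt(max(abs(kap_h[2:99] - 0.8)) / 0.8, 0.01)

  line <- cbind(seq(0, 1, length.out = 30), 0, 0)
  expect_equal(curvature_profile(line), rep(0, 30))
  expect_equal(suppressWarnings(torsion_profile(line)), rep(0, 30))

  # planar S-curve carries no torsion, including across its inflection
  expect_lt(max(torsion_profile(fixtures$s_curve)), 1e-6)
})

test_that("profiles scale inversely with coordinate scale", {
  for (c_ in c(0.1, 5)) {
    expect_equal(curvature_profile(fixtures$helix * c_),
                 curvature_profile(fixtures$helix) / c_, tolerance = 1e-9)
    expect_equal(torsion_profile(fixtures$helix * c_),
                 torsion_profile(fixtures$helix) / c_, tolerance = 1e-9)
  }
})

test_that("bend point finds a planted curvature maximum and fails on flat curves", {
  # planar curve with a single curvature bump centered at s = 0.4
  s <- seq(0, 1, length.out = 400)
  bump <- 6 * exp(-0.5 * ((s - 0.4) / 0.05)^2)
  curve <- frenet_reconstruct(bump, NULL, length = 1)
  expect_equal(bend_point(curve), 0.4, tolerance = 1.5 / 99)

  expect_error(bend_point(cbind(seq(0, 1, length.out = 50), 0, 0)),
               class = "kinprims_no_bend")

  # constant curvature: every index ties; the most proximal maximum wins,
  # deterministically
  b1 <- bend_point(fixtures$circle_r1)
  expect_identical(b1, bend_point(fixtures$circle_r1))
})

test_that("elongation ratio tracks a travelling bend monotonically", {
  tb <- gaussian_units(w = 0.4, mu_s = 0.5, mu_t = 0.5,
                       sigma_ss = 0.02, sigma_tt = 0.05, sigma_st = 0.025)
  mv <- sim_movement(tb, NULL, n = 100, m = 20)
  er <- elongation_ratio(mv$curves)
  expect_equal(nrow(er), 20)
  expect_true(all(er$ratio > 0 & er$ratio < 1))
  expect_true(all(diff(er$ratio) >= -1e-9))

  # a bend planted at s = 0.5 sits halfway along the (uniform) arm
  mid <- gaussian_units(0.4, 0.5, 0.5, 0.005, 0.05)
  mv2 <- sim_movement(mid, NULL, n = 100, m = 5)
  er2 <- elongation_ratio(mv2$curves)
  expect_equal(er2$ratio, rep(0.5, 5), tolerance = 1.5 / 99)
})
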