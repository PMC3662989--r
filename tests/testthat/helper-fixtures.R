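# Shared helpers for the test suite.  All fixtures are generated in code.

fixtures <- kin_fixtures()

random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

rigid_transform <- function(curves, rotation, translation) {
  xyz <- as.matrix(curves[c("x", "y", "z")]) %*% t(rotation)
  curves$x <- xyz[, 1] + translation[1]
  curves$y <- xyz[, 2] + translation[2]
  curves$z <- xyz[, 3] + translation[3]
  curves
}

# adjusted Rand index between two labelings (oracle from mclust when
# available, otherwise the closed-form pair-counting formula)
ari <- function(a, b) {
  if (requireNamespace("mclust", quietly = TRUE)) {
    return(mclust::adjustedRandIndex(a, b))
  }
  tab <- table(a, b)
  comb2 <- function(x) sum(choose(x, 2))
  n <- length(a)
  idx <- comb2(as.vector(tab))
  e1 <- comb2(rowSums(tab))
  e2 <- comb2(colSums(tab))
  expected <- e1 * e2 / choose(n, 2)
  (idx - expected) / ((e1 + e2) / 2 - expected)
}

# curvature/torsion units with overlapping support: the reconstructable
# regime for curvature-torsion round trips
roundtrip_units <- function() {
  list(
    curvature = gaussian_units(
      w = c(2.0, 0.8), mu_s = c(0.45, 0.7), mu_t = c(0.45, 0.6),
      sigma_ss = c(0.050, 0.010), sigma_tt = c(0.080, 0.015),
      sigma_st = c(0, 0.006)
    ),
    torsion = gaussian_units(
      w = c(0.5, 0.3), mu_s = c(0.45, 0.55), mu_t = c(0.40, 0.60),
      sigma_ss = c(0.012, 0.010), sigma_tt = c(0.020, 0.015),
      sigma_st = 0
    )
  )
}
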