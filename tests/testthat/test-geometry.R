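test_that("sphericity ratio reproduces the sphere-adequacy identities", {
  # end-systolic and end-diastolic population indices
  expect_close(sphericity_ratio(2), 0.5 * sqrt(5), 1e-12)
  expect_equal(trunc(sphericity_ratio(2) * 100) / 100, 1.11)
  expect_equal(trunc(sphericity_ratio(1.7) * 100) / 100, 0.98)
  expect_equal(sphericity_ratio(sqrt(3)), 1)
  # exact identity over a grid
  x <- seq(0.2, 5, by = 0.1)
  expect_true(all(abs(sphericity_ratio(x)^2 - 0.25 * (x^2 + 1)) < 1e-14))
  expect_error(sphericity_ratio(0), "positive")
  expect_error(sphericity_ratio(-1), "positive")
})

test_that("eccentricity half-ratio behaves", {
  expect_equal(eccentricity_half(2), 1)
  expect_equal(eccentricity_half(1.8), 0.9)
  expect_equal(eccentricity_half(1), 0.5)
  expect_error(eccentricity_half(0.9), ">= 1")
})

test_that("radial profile extraction covers the grid and interpolates", {
  v <- scalar_volume(array(3, dim = c(24, 24, 24)), spacing = 4)
  ctr <- c(46, 46, 46)
  p <- extract_radial_profiles(v, ctr, 48, 96, step = 2, max_radius = 30)
  expect_equal(nrow(p$samples), 48 * 96)
  p2 <- extract_radial_profiles(v, ctr, 120, 320, step = 2, max_radius = 30)
  expect_equal(nrow(p2$samples), 120 * 320)
  # constant volume: every interior sample equals the constant
  expect_true(all(abs(p$samples[, p$radii <= 40] - 3) < 1e-12))
  # linearity in the counts
  v2 <- scalar_volume(v$data * 7, spacing = 4)
  p3 <- extract_radial_profiles(v2, ctr, 6, 6, step = 2, max_radius = 30)
  p1 <- extract_radial_profiles(v, ctr, 6, 6, step = 2, max_radius = 30)
  expect_equal(p3$samples, 7 * p1$samples, tolerance = 1e-12)
  expect_error(extract_radial_profiles(v, c(-5, 0, 0), 4, 4),
               "outside")
})

test_that("zero padding outside the grid", {
  v <- scalar_volume(array(5, dim = c(16, 16, 16)), spacing = 1)
  expect_equal(interp_trilinear(v, c(100, 100, 100)), 0)
  expect_equal(interp_trilinear(v, c(7, 7, 7)), 5)
})

test_that("algebraic sphere fit recovers exact spheres and is equivariant", {
  pts <- rbind(c(6, 2, 3), c(-4, 2, 3), c(1, 7, 3),
               c(1, -3, 3), c(1, 2, 8), c(1, 2, -2))
  s <- fit_sphere_least_squares(pts)
  expect_equal(s$center, c(1, 2, 3), tolerance = 1e-10)
  expect_equal(s$radius, 5, tolerance = 1e-10)

  # >= 20 exact on-sphere points: radius to machine-level precision
  set.seed(42)
  d <- matrix(rnorm(3 * 40), ncol = 3)
  d <- d / sqrt(rowSums(d^2))
  pts2 <- sweep(25 * d, 2, c(10, -5, 0), "+")
  s2 <- fit_sphere_least_squares(pts2)
  expect_close(s2$radius, 25, 1e-6)

  # translation equivariance
  t0 <- c(13.7, -2.2, 8.1)
  s3 <- fit_sphere_least_squares(sweep(pts2, 2, t0, "+"))
  expect_equal(s3$center, s2$center + t0, tolerance = 1e-8)
  expect_equal(s3$radius, s2$radius, tolerance = 1e-8)

  # coplanar points are degenerate
  flat <- cbind(matrix(runif(20), ncol = 2), 3)
  expect_error(fit_sphere_least_squares(flat), "degenerate|coplanar")
  expect_error(fit_sphere_least_squares(pts[1:3, ]), "at least 4")
})

test_that("algebraic sphere fit matches a brute-force geometric oracle", {
  set.seed(7)
  d <- matrix(rnorm(3 * 200), ncol = 3)
  d <- d / sqrt(rowSums(d^2))
  pts <- sweep(25 * d, 2, c(10, -5, 0), "+") + matrix(rnorm(600), ncol = 3)
  fit <- fit_sphere_least_squares(pts)

  # oracle: grid minimiser of the summed squared geometric residuals,
  # coarse-to-fine down to a 0.1 mm grid
  ss <- function(cx, cy, cz, r) {
    sum((sqrt((pts[, 1] - cx)^2 + (pts[, 2] - cy)^2 +
                (pts[, 3] - cz)^2) - r)^2)
  }
  ctr0 <- colMeans(pts)
  r0 <- mean(sqrt(rowSums(sweep(pts, 2, ctr0)^2)))
  best <- c(ctr0, r0); bv <- Inf
  for (step in c(0.5, 0.1)) {
    g <- seq(-4 * step, 4 * step, by = step)
    for (ax in best[1] + g) for (ay in best[2] + g)
      for (az in best[3] + g) for (ar in best[4] + g) {
        v <- ss(ax, ay, az, ar)
        if (v < bv) { bv <- v; cand <- c(ax, ay, az, ar) }
      }
    best <- cand
  }
  expect_lt(max(abs(fit$center - best[1:3])), 0.5)
  expect_lt(abs(fit$radius - best[4]), 0.5)
})

test_that("ellipsoid fit recovers exact and noisy ellipsoids", {
  set.seed(11)
  n <- 400
  th <- acos(runif(n, -1, 1)); ph <- runif(n, 0, 2 * pi)
  u <- cbind(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
  pts <- sweep(u %*% diag(c(20, 30, 45)), 2, c(5, -3, 12), "+")
  m <- fit_ellipsoid_least_squares(pts)
  expect_equal(m$semi_axes, c(20, 30, 45), tolerance = 0.1 / 20)
  expect_equal(m$center, c(5, -3, 12), tolerance = 1e-4)

  noisy <- pts + matrix(rnorm(3 * n), ncol = 3)
  m2 <- fit_ellipsoid_least_squares(noisy)
  expect_true(all(abs(m2$semi_axes - c(20, 30, 45)) < 1))

  expect_error(fit_ellipsoid_least_squares(pts[1:8, ]), "at least 9")
})

test_that("moment ellipsoid gives a usable shell-scaled initialiser", {
  set.seed(3)
  n <- 2000
  th <- acos(runif(n, -1, 1)); ph <- runif(n, 0, 2 * pi)
  u <- cbind(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
  pts <- sweep(u * 30, 2, c(1, 2, 3), "+")
  m <- moment_ellipsoid(pts)
  expect_equal(m$center, c(1, 2, 3), tolerance = 0.5)
  expect_true(all(abs(m$semi_axes - 30) < 2))
})
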