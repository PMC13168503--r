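test_that("limiting cases of the moment model", {
  expect_equal(unname(moments_from_orientation(90, 0, 0)), c(1, 0, 0, 0),
               tolerance = 1e-12)
  expect_equal(unname(moments_from_orientation(37, 111, 180)),
               c(1, 1, 1, 0) / 3, tolerance = 1e-12)
  expect_error(moments_from_orientation(100, 0, 0))
  expect_error(moments_from_orientation(45, 0, 200))
})

test_that("cone-average closed form matches the Monte-Carlo oracle", {
  # frozen oracle: 1e6 uniform solid-angle draws in the cone (seed 42),
  # mean direction (eta 45, xi 30), full apex 100 degrees
  oracle <- c(xx = 0.355938, yy = 0.223303, zz = 0.420759, xy = 0.114532)
  m <- moments_from_orientation(45, 30, 100)
  expect_lt(max(abs(m - oracle)), 1e-3)
})

test_that("gamma is strictly decreasing from 1 to 0", {
  d <- seq(0, 180, by = 1)
  g <- gamma_delta(d)
  expect_equal(g[1], 1)
  expect_equal(g[length(g)], 0)
  expect_true(all(diff(g) < 0))
})

test_that("orientation retrieval is exact on the model manifold", {
  set.seed(5)
  eta <- runif(400, 2, 88); xi <- runif(400, 0, 180); delta <- runif(400, 5, 175)
  m <- moments_from_orientation(eta, xi, delta)
  ang <- orientation_from_moments(m)
  expect_lt(max(abs(ang$eta - eta)), 0.01)
  expect_lt(max(abs(fold90(ang$xi - xi))), 0.01)
  expect_lt(max(abs(ang$delta - delta)), 0.01)
})

test_that("isotropic moments retrieve full wobble with an ill-defined azimuth", {
  ang <- orientation_from_moments(c(1, 1, 1, 0) / 3)
  expect_equal(ang$delta, 180, tolerance = 1e-6)
  expect_true(ang$ill_defined)
})

test_that("intensity inversion round-trips and validates input", {
  K <- test_bank()$K
  m <- moments_from_orientation(50, 120, 100)
  I <- as.vector(K %*% m)
  m2 <- invert_intensities(I, K)
  expect_equal(unname(unlist(m2[1, 1:4])), unname(m), tolerance = 1e-9)
  expect_false(m2$clipped)
  expect_error(invert_intensities(c(-1, 5, 5, 5), K), "non-negative")
  expect_error(invert_intensities(c(0, 0, 0, 0), K), "empty signal")
  expect_error(invert_intensities(c(1, 1, 1, 1), matrix(0, 4, 4)), "singular")
})

test_that("noisy inversion is unbiased at the moment level", {
  K <- test_bank()$K
  q <- test_bank()$q
  m <- moments_from_orientation(45, 30, 100)
  Ipred <- as.vector(K %*% m) / sum(q * m) * 5000
  set.seed(1)
  I <- matrix(rpois(4 * 3000, rep(Ipred, each = 3000)), ncol = 4)
  colnames(I) <- c("I0", "I90", "I45", "I135")
  mm <- invert_intensities(I, K)
  bias <- colMeans(as.matrix(mm[, 1:4])) - m
  expect_lt(max(abs(bias)), 0.01)
})

test_that("projection into the physical set never increases the forward residual", {
  K <- test_bank()$K
  set.seed(9)
  for (r in 1:50) {
    I <- rexp(4, 1 / 500)
    mm <- invert_intensities(I, K)
    raw <- unlist(mm[1, paste0("raw_", c("xx", "yy", "zz", "xy"))])
    raw <- raw / sum(raw[1:3])
    proj <- unlist(mm[1, c("xx", "yy", "zz", "xy")])
    dist_to_manifold <- function(m4) {
      f <- function(p) sum((moments_from_orientation(p[1], p[2], p[3]) - m4)^2)
      stats::optim(c(45, 45, 90), f, method = "L-BFGS-B",
                   lower = c(0, -45, 0), upper = c(90, 225, 180))$value
    }
    if (mm$clipped[1] && all(is.finite(raw))) {
      expect_lte(dist_to_manifold(proj), dist_to_manifold(raw) + 1e-6)
    }
  }
})

test_that("ratiometric observables follow the expected symmetries and trends", {
  bank <- test_bank()
  K <- bank$K
  # fixed in-plane dipole along x: P45 zero, P0 maximal over xi
  p0s <- sapply(seq(0, 90, by = 15), function(xi) {
    I <- as.vector(K %*% moments_from_orientation(90, xi, 0))
    ratiometric_observables(I)$P0
  })
  I0 <- as.vector(K %*% moments_from_orientation(90, 0, 0))
  expect_equal(ratiometric_observables(I0)$P45, 0, tolerance = 1e-9)
  expect_equal(unname(which.max(p0s)), 1L)
  # isotropic: both polarization ratios vanish
  ri <- ratiometric_observables(as.vector(K %*% c(1, 1, 1, 0) / 3))
  expect_equal(ri$P0, 0, tolerance = 1e-9)
  expect_equal(ri$P45, 0, tolerance = 1e-9)
  # R_NA strictly monotone in eta at fixed wobble
  rna <- sapply(seq(0, 90, by = 5), function(e) {
    I <- as.vector(K %*% moments_from_orientation(e, 20, 0))
    ratiometric_observables(I)$R_NA
  })
  expect_true(all(diff(rna) > 0))
  # polarization magnitude strictly decreasing in delta
  pm <- sapply(seq(0, 180, by = 10), function(d) {
    r <- ratiometric_observables(as.vector(K %*% moments_from_orientation(70, 25, d)))
    r$P0^2 + r$P45^2
  })
  expect_true(all(diff(pm) < 1e-12))
  # zero denominator flagged
  expect_true(ratiometric_observables(c(0, 0, 1, 1))$undefined)
})

test_that("retrieved azimuth is equivariant under sample rotation", {
  bank <- test_bank()
  K <- bank$K
  base <- c(55, 20, 80)
  for (phi in c(15, 40, 90, 130)) {
    I <- as.vector(K %*% moments_from_orientation(base[1], base[2] + phi, base[3]))
    ang <- orientation_from_moments(invert_intensities(I, K)[, 1:4])
    expect_equal(fold90(ang$xi - (base[2] + phi)), 0, tolerance = 1e-6)
  }
})

test_that("known-brightness ML retrieval matches the analytic chain on clean data", {
  bank <- test_bank()
  for (ang in list(c(25, 10, 60), c(70, 100, 130))) {
    I <- predict_intensities(bank, ang[1], ang[2], ang[3], 5000)
    ml <- orientation_ml(I, bank$K, q = bank$q, photons = 5000)
    expect_equal(ml$eta, ang[1], tolerance = 0.1)
    expect_equal(fold90(ml$xi - ang[2]), 0, tolerance = 0.1)
    expect_equal(ml$delta, ang[3], tolerance = 0.5)
  }
})
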