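test_that("diagonal basis images are non-negative and cross-term integrals vanish", {
  bank <- test_bank()
  b <- basis_psfs(bank = bank)
  for (ci in 1:4) {
    for (j in c("xx", "yy", "zz")) {
      expect_true(all(b$B[, , j, ci] >= -1e-12))
    }
    ref <- sum(b$B[, , "xx", ci])
    expect_lt(abs(sum(b$B[, , "xz", ci])), 1e-6 * ref)
    expect_lt(abs(sum(b$B[, , "yz", ci])), 1e-6 * ref)
  }
  expect_true(is.finite(b$cond))
  expect_lt(b$cond, 100)
})

test_that("integrated K matches the analytic radial-quadrature oracle within 0.5%", {
  bank <- test_bank()
  Ko <- K_radial_oracle(bank$config)
  rel <- (bank$K / bank$K[1, 1]) / (Ko / Ko[1, 1])
  # compare entries that are not numerically zero
  big <- abs(Ko / Ko[1, 1]) > 1e-3
  expect_lt(max(abs(rel[big] - 1)), 0.005)
})

test_that("isotropic moments give balanced channel pairs", {
  bank <- test_bank()
  m <- c(1, 1, 1, 0) / 3
  I <- as.vector(bank$K %*% m)
  expect_equal(I[1], I[2], tolerance = 1e-9)
  expect_equal(I[3], I[4], tolerance = 1e-9)
})

test_that("the arm ratio separates in-plane from vertical dipoles", {
  bank <- test_bank()
  Iz <- as.vector(bank$K %*% c(0, 0, 1, 0))
  Ix <- as.vector(bank$K %*% c(1, 0, 0, 0))
  r <- function(I) (I[1] + I[2]) / (I[3] + I[4])
  expect_gt(r(Ix), r(Iz))
})

test_that("rendered PSFs are linear in photons and consistent with the window matrix", {
  bank <- test_bank()
  m <- moments_from_orientation(60, 20, 90, all_six = TRUE)
  a <- psf_from_moments(m, 5000, bank, position = c(7, 7))
  b <- psf_from_moments(m, 10000, bank, position = c(7, 7))
  for (ch in names(a)) expect_equal(2 * a[[ch]], b[[ch]], tolerance = 1e-12)
  got <- sapply(a, sum)
  pred <- as.vector(bank$K_window %*% m[1:4]) / sum(bank$q * m[1:4]) * 5000
  expect_equal(unname(got), pred, tolerance = 1e-9)
  # full-plane prediction differs only by the window truncation
  pred_full <- as.vector(bank$K %*% m[1:4]) / sum(bank$q * m[1:4]) * 5000
  expect_true(all(got < pred_full) && all(got > 0.75 * pred_full))
})

test_that("an in-plane wobbling molecule favours its co-polarized channel", {
  bank <- test_bank()
  m <- moments_from_orientation(90, 0, 100, all_six = TRUE)
  img <- psf_from_moments(m, 5000, bank)
  peaks <- sapply(img, max)
  # within the low-NA pair the co-polarized channel dominates strongly,
  # and the 45/135 pair is balanced by symmetry
  expect_gt(peaks[["I0"]], 3 * peaks[["I90"]])
  expect_equal(peaks[["I45"]], peaks[["I135"]], tolerance = 1e-9)
})

test_that("requested positions snap to the rendering lattice", {
  bank <- test_bank()
  img <- psf_from_moments(c(xx = 1, yy = 0, zz = 0, xy = 0), 1000, bank,
                          position = c(7.31, 6.84))
  snapped <- attr(img, "position")
  expect_equal(snapped, c(7.375, 6.875) - c(0.0625, 0), tolerance = 0.0626)
  expect_lt(max(abs(snapped - c(7.31, 6.84))), 0.5 / bank$oversample + 1e-9)
  expect_error(psf_from_moments(c(xx = 1, yy = 0, zz = 0, xy = 0), 1000,
                                bank, position = c(40, 2)), "outside")
})

test_that("total rendered energy is invariant under azimuth rotation", {
  bank <- test_bank()
  tot <- sapply(c(0, 30, 75, 120, 160), function(xi) {
    m <- moments_from_orientation(55, xi, 80, all_six = TRUE)
    sum(sapply(psf_from_moments(m, 5000, bank), sum))
  })
  expect_lt(diff(range(tot)) / mean(tot), 0.001)
})

test_that("swapping m_xx and m_yy swaps the paired channels", {
  bank <- test_bank()
  m1 <- c(xx = 0.55, yy = 0.25, zz = 0.2, xy = 0)
  m2 <- c(xx = 0.25, yy = 0.55, zz = 0.2, xy = 0)
  I1 <- as.vector(bank$K %*% m1)
  I2 <- as.vector(bank$K %*% m2)
  expect_equal(I1[1], I2[2], tolerance = 1e-9)
  expect_equal(I1[2], I2[1], tolerance = 1e-9)
  expect_equal(I1[3], I2[4], tolerance = 1e-9)
  expect_equal(I1[4], I2[3], tolerance = 1e-9)
})

test_that("ratiometric observables are robust to 200 nm defocus", {
  cfg0 <- optical_config(pupil_samples = 128)
  cfg2 <- optical_config(pupil_samples = 128, z1 = 200)
  b0 <- psf_bank(cfg0, oversample = 2)
  b2 <- psf_bank(cfg2, oversample = 2)
  for (ang in list(c(30, 0, 60), c(60, 45, 100), c(80, 120, 140))) {
    m <- moments_from_orientation(ang[1], ang[2], ang[3])
    r0 <- ratiometric_observables(as.vector(b0$K %*% m))
    r2 <- ratiometric_observables(as.vector(b2$K %*% m))
    expect_lt(abs(r2$R_NA - r0$R_NA) / r0$R_NA, 0.01)
    expect_lt(abs(r2$P0 - r0$P0), 0.01)
    expect_lt(abs(r2$P45 - r0$P45), 0.01)
  }
})

test_that("aberrations deform the PSF without destroying its energy budget", {
  cfg <- optical_config(pupil_samples = 128)
  b0 <- psf_bank(cfg, oversample = 2)
  ba <- psf_bank(cfg, oversample = 2,
                 aberration = aberration_spec(zernike = c("5" = 0.6)))
  m <- moments_from_orientation(90, 0, 100, all_six = TRUE)
  i0 <- psf_from_moments(m, 5000, b0)
  ia <- psf_from_moments(m, 5000, ba)
  expect_gt(max(abs(i0$I0 - ia$I0)), 1)     # shapes differ
  expect_equal(sum(sapply(i0, sum)), sum(sapply(ia, sum)), tolerance = 0.02)
})
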