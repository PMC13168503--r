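# synthetic polarizer series generated directly from a K matrix
series_from_K <- function(K, angles = seq(0, 180, by = 15), gains = rep(1, 4),
                          noise_photons = NULL) {
  Kg <- diag(gains) %*% K
  rows <- lapply(angles, function(th) {
    t_ <- th * pi / 180
    m <- c(cos(t_)^2, sin(t_)^2, 0, sin(t_) * cos(t_))
    I <- as.vector(Kg %*% m)
    if (!is.null(noise_photons)) {
      I <- rpois(4, I / sum(I) * noise_photons) * sum(I) / noise_photons
    }
    c(angle_deg = th, stats::setNames(I, c("I0", "I90", "I45", "I135")))
  })
  tibble::as_tibble(do.call(rbind, rows))
}

unpol_from_K <- function(K, gains = rep(1, 4)) {
  stats::setNames(as.vector(diag(gains) %*% K %*% c(1, 1, 1, 0) / 3),
                  c("I0", "I90", "I45", "I135"))
}

test_that("noise-free polarizer series recovers the generating matrix", {
  K <- test_bank()$K
  cal <- calibrate_K(series_from_K(K), unpol_from_K(K))
  expect_equal(unname(cal$K), unname(K), tolerance = 1e-6)
  expect_equal(cal$provenance, "measured")
})

test_that("the zz column is unidentifiable without the unpolarized frame", {
  K <- test_bank()$K
  expect_error(calibrate_K(series_from_K(K)), "degeneracy")
})

test_that("series shorter than the protocol are rejected", {
  K <- test_bank()$K
  s <- series_from_K(K, angles = seq(0, 90, by = 7.5))
  expect_error(calibrate_K(s, unpol_from_K(K)), "180")
  s2 <- series_from_K(K, angles = c(0, 60, 120, 180))
  expect_error(calibrate_K(s2, unpol_from_K(K)), "8")
})

test_that("channel gains are absorbed and leave retrieval unbiased", {
  K <- test_bank()$K
  gains <- c(1.0, 0.95, 1.08, 0.9)
  cal <- calibrate_K(series_from_K(K, gains = gains),
                     unpol_from_K(K, gains = gains))
  errs <- sapply(list(c(30, 20, 70), c(55, 100, 120), c(75, 160, 90)),
                 function(ang) {
    m <- moments_from_orientation(ang[1], ang[2], ang[3])
    I <- gains * as.vector(K %*% m)          # molecule seen through the gains
    a <- orientation_from_moments(invert_intensities(I, cal$K)[, 1:4])
    max(abs(a$eta - ang[1]), abs(fold90(a$xi - ang[2])), abs(a$delta - ang[3]))
  })
  expect_lt(mean(errs), 1)
})

test_that("Poisson calibration noise stays within its standard errors", {
  K <- test_bank()$K
  set.seed(41)
  cover <- replicate(40, {
    s <- series_from_K(K, noise_photons = 1e5)
    up <- unpol_from_K(K)
    cal <- calibrate_K(s, up)
    inplane <- c("xx", "yy", "xy")
    all(abs(cal$K[, inplane] - K[, inplane]) <=
          pmax(3 * cal$se[, inplane], 1e-6 * max(K)))
  })
  expect_gt(mean(cover), 0.85)
})

test_that("gain rescaling of one channel leaves retrieved angles unchanged", {
  K <- test_bank()$K
  K2 <- K; K2[2, ] <- 1.3 * K2[2, ]
  m <- moments_from_orientation(50, 70, 110)
  I2 <- as.vector(K2 %*% m)
  ang <- orientation_from_moments(invert_intensities(I2, K2)[, 1:4])
  expect_equal(ang$eta, 50, tolerance = 1e-6)
  expect_equal(ang$delta, 110, tolerance = 1e-6)
})

test_that("calibration JSON round-trips", {
  cal <- test_cal()
  p <- withr::local_tempfile(fileext = ".json")
  write_calibration(cal, p)
  cal2 <- read_calibration(p)
  expect_equal(cal2$K, cal$K, tolerance = 1e-12)
  expect_equal(cal2$provenance, cal$provenance)
})

# ---- channel registration ----------------------------------------------

bead_image <- function(centers, size = 96, photons = 4e4, sigma = 1.2) {
  g <- seq(0, size - 1)
  img <- matrix(5, size, size)
  for (k in seq_len(nrow(centers))) {
    img <- img + photons / (2 * pi * sigma^2) *
      outer(g, g, function(x, y)
        exp(-((x - centers[k, 1])^2 + (y - centers[k, 2])^2) / (2 * sigma^2)))
  }
  img
}

test_that("identical bead stacks register to the identity", {
  set.seed(51)
  centers <- cbind(runif(14, 10, 85), runif(14, 10, 85))
  img <- bead_image(centers)
  tfs <- fit_channel_registration(list(I0 = img, I90 = img, I45 = img,
                                       I135 = img))
  for (ch in c("I90", "I45", "I135")) {
    expect_equal(tfs[[ch]]$A, diag(2), tolerance = 1e-3)
    expect_lt(sqrt(sum(tfs[[ch]]$b^2)), 0.02)
    expect_lt(tfs[[ch]]$residual_rms_nm, 5)
  }
})

test_that("a known affine distortion is recovered to 0.05 px", {
  set.seed(52)
  centers <- cbind(runif(16, 12, 82), runif(16, 12, 82))
  th <- 0.5 * pi / 180
  A <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
  off <- c(3.2, -1.7)
  moved <- t(A %*% t(centers)) + matrix(off, nrow(centers), 2, byrow = TRUE)
  imgs <- list(I0 = bead_image(centers), I90 = bead_image(moved),
               I45 = bead_image(centers), I135 = bead_image(centers))
  tfs <- fit_channel_registration(imgs)
  # transform maps channel coordinates into the reference
  back <- apply_affine(moved, tfs$I90)
  expect_lt(sqrt(mean(rowSums((back - centers)^2))), 0.05)
})

test_that("an empty channel raises the insufficient-landmark error", {
  set.seed(53)
  centers <- cbind(runif(12, 10, 85), runif(12, 10, 85))
  imgs <- list(I0 = bead_image(centers), I90 = matrix(5, 96, 96),
               I45 = bead_image(centers), I135 = bead_image(centers))
  expect_error(fit_channel_registration(imgs), "insufficient landmarks")
})

test_that("pairing refinement corrects a residual offset and skips tiny sets", {
  tfs <- identity_transforms()
  set.seed(54)
  res <- list(I90 = cbind(rnorm(300, 0.3, 0.02), rnorm(300, -0.1, 0.02)))
  out <- refine_pairing_offset(res, tfs)
  expect_true(attr(out, "refined"))
  expect_equal(out$I90$b, c(-0.3, 0.1), tolerance = 0.05)
  expect_warning(refine_pairing_offset(list(I90 = res$I90[1:50, ]), tfs),
                 "skipped")
  # zero systematic offset leaves transforms numerically unchanged
  res0 <- list(I90 = cbind(rnorm(300, 0, 0.02), rnorm(300, 0, 0.02)))
  out0 <- refine_pairing_offset(res0, tfs)
  expect_lt(sqrt(sum(out0$I90$b^2)), 0.01)
})

# ---- drift correction --------------------------------------------------

filament_table <- function(n_frames, drift_per_frame = c(0, 0), seed = 61) {
  set.seed(seed)
  n <- n_frames * 8
  fr <- sample.int(n_frames, n, replace = TRUE)
  t_ <- runif(n)
  onA <- runif(n) < 0.5
  x <- ifelse(onA, 1000 + t_ * 4000, 2000 + t_ * 1500)
  y <- ifelse(onA, 2000 + t_ * 800, 500 + t_ * 4200)
  tibble::tibble(frame = fr,
                 x_nm = x + rnorm(n, 0, 15) + drift_per_frame[1] * fr,
                 y_nm = y + rnorm(n, 0, 15) + drift_per_frame[2] * fr)
}

test_that("zero injected drift yields near-zero correction", {
  tab <- filament_table(4000)
  out <- drift_correct(tab, frames_per_bin = 1000)
  d <- attr(out, "drift")
  expect_lt(max(abs(c(d$dx_nm, d$dy_nm))), 5)
})

test_that("a one-micron linear drift is corrected to better than 20 nm RMS", {
  nfr <- 6000
  rate <- c(1000 / nfr, 600 / nfr)          # ~1 um over the stack
  tab <- filament_table(nfr, drift_per_frame = rate, seed = 62)
  out <- drift_correct(tab, frames_per_bin = 1000)
  d <- attr(out, "drift")
  resid <- cbind(d$dx_nm - (rate[1] * d$frame - mean(rate[1] * d$frame)),
                 d$dy_nm - (rate[2] * d$frame - mean(rate[2] * d$frame)))
  resid <- sweep(resid, 2, colMeans(resid))
  expect_lt(sqrt(mean(resid^2)), 20)
})

test_that("a single temporal bin cannot be drift-corrected", {
  tab <- filament_table(500)
  expect_error(drift_correct(tab, frames_per_bin = 1000), "2 temporal bins")
})
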