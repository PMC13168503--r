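loc_table <- function(n = 100, eta = 45, xi = 0, delta = 100, photons = 4000,
                      radius = 1.2, seed = 1) {
  set.seed(seed)
  tibble::tibble(id = seq_len(n), frame = 1L,
                 x_nm = runif(n, 0, 4000), y_nm = runif(n, 0, 4000),
                 eta = rep_len(eta, n), xi = rep_len(xi, n),
                 delta = rep_len(delta, n), photons = rep_len(photons, n),
                 radius_px = rep_len(radius, n), ill_defined = FALSE)
}

test_that("confidence filtering applies the published ranges", {
  tab <- loc_table(6)
  tab$eta <- c(89, 45, 45, 45, 4, 45)
  tab$delta <- c(100, 3, 100, 100, 100, 176)
  tab$photons <- c(5000, 5000, 900, 1001, 5000, 5000)
  out <- filter_confidence(tab)
  expect_equal(out$id, 4L)
  rej <- attr(out, "rejections")
  expect_equal(unname(rej["eta_range"]), 2)
  expect_equal(unname(rej["delta_range"]), 2)
  expect_equal(unname(rej["low_photons"]), 1)
  # empty input stays empty with zero counts
  e <- filter_confidence(tab[0, ])
  expect_equal(nrow(e), 0)
  expect_true(all(attr(e, "rejections") == 0))
})

test_that("polar-angle binning implements both published schemes with lower-bin ties", {
  tab <- loc_table(5)
  tab$eta <- c(25, 50, 60, 61, 35)
  b1 <- bin_eta(tab, "fig2")
  expect_equal(as.character(b1$eta_bin),
               c("off_plane", "intermediate", "intermediate", "in_plane",
                 "intermediate"))
  b2 <- bin_eta(tab, "cell")
  expect_equal(as.character(b2$eta_bin)[c(1, 5)],
               c("off_plane", "off_plane"))
  expect_error(bin_eta(tab, "other"))
  # partition: exactly one label per record
  expect_false(any(is.na(b1$eta_bin)))
})

test_that("misclassification rates are zero on perfect retrieval and one under shifts", {
  tab <- loc_table(60)
  tab$eta <- runif(60, 0, 90)
  r0 <- misclassification_rates(tab, tab)
  expect_true(all(r0$wrong_fraction[r0$n_truth > 0] == 0))
  shifted <- tab
  shifted$eta <- pmin(tab$eta + 90, 90)
  r1 <- misclassification_rates(shifted, tab)
  off <- r1$wrong_fraction[r1$class == "off_plane"]
  expect_equal(off, 1)
  expect_error(misclassification_rates(tab, dplyr::mutate(tab, id = id + 1000)),
               "matching")
})

test_that("radiality of a perfectly radial scene saturates and a random one hits the null", {
  set.seed(81)
  n <- 4000
  d <- runif(n, 30, 800)
  th <- runif(n, 0, 2 * pi)
  tab <- tibble::tibble(x_nm = 1000 + d * cos(th), y_nm = 1000 + d * sin(th))
  roi <- roi_spec(1000, 1000, 900)
  rad <- dplyr::mutate(tab, xi = (th * 180 / pi) %% 180)
  pr <- radiality_profile(rad, roi, step_nm = 100)
  expect_true(all(pr$fraction_radial > 0.999))
  unif <- dplyr::mutate(tab, xi = runif(n, 0, 180))
  pu <- radiality_profile(unif, roi, step_nm = 100)
  # uniform azimuths: fraction equals 2*cutoff/180 within 3 sigma binomially
  for (k in seq_len(nrow(pu))) {
    p0 <- pu$null_fraction[k]
    se <- sqrt(p0 * (1 - p0) / pu$n[k])
    expect_lt(abs(pu$fraction_radial[k] - p0), 3 * se + 1e-9)
  }
})

test_that("a radial ring with a vertical core reproduces the podosome signature", {
  set.seed(82)
  ring_n <- 1500; core_n <- 700
  th <- runif(ring_n, 0, 2 * pi)
  d <- rnorm(ring_n, 400, 40)
  ring <- tibble::tibble(x_nm = d * cos(th), y_nm = d * sin(th),
                         xi = (th * 180 / pi) %% 180,
                         eta = runif(ring_n, 65, 90))
  thc <- runif(core_n, 0, 2 * pi); dc <- abs(rnorm(core_n, 0, 120))
  core <- tibble::tibble(x_nm = dc * cos(thc), y_nm = dc * sin(thc),
                         xi = runif(core_n, 0, 180),
                         eta = runif(core_n, 5, 35))
  tab <- dplyr::bind_rows(ring, core)
  roi <- roi_spec(0, 0, 700, "in")
  pr <- radiality_profile(tab, roi, step_nm = 50)
  peak_d <- pr$d_bin_nm[which.max(pr$fraction_radial)]
  expect_true(peak_d >= 300 && peak_d <= 500)
  ef <- eta_fraction_profile(tab, roi, step_nm = 100)
  expect_equal(ef$d_bin_nm[which.max(ef$frac_off_plane)], 0)
})

test_that("localizations at the exact ROI center are excluded", {
  tab <- tibble::tibble(x_nm = c(0, 100), y_nm = c(0, 0),
                        xi = c(0, 0), eta = c(45, 45))
  pr <- radiality_profile(tab, roi_spec(0, 0, 500), step_nm = 50)
  expect_equal(sum(pr$n), 1)
})

test_that("focus classes follow the published thresholds", {
  tab <- tibble::tibble(eta = c(70, 30, 50, 70, 30),
                        radius_px = c(1.2, 2.3, 1.7, 2.5, 1.2))
  fc <- focus_classes(tab)
  expect_equal(as.character(fc$focus_class),
               c("in_plane_in_focus", "off_plane_off_focus", "other",
                 "other", "other"))
})

test_that("stick maps are deterministic and oriented along the azimuth", {
  tab <- tibble::tibble(x_nm = 500, y_nm = 500, xi = 0, eta = 45, delta = 90)
  img1 <- render_stick_map(tab, "eta", stick_length_nm = 100, pixel_nm = 20)
  img2 <- render_stick_map(tab, "eta", stick_length_nm = 100, pixel_nm = 20)
  expect_identical(img1, img2)
  lit <- which(apply(img1, c(1, 2), max) > 0, arr.ind = TRUE)
  # a horizontal stick: spread along x, single row in y
  expect_gt(diff(range(lit[, 1])), 3)
  expect_equal(length(unique(lit[, 2])), 1)
  expect_error(render_stick_map(tab[0, ]), "empty")
})

test_that("a 70-degree filament crossing gives a bimodal azimuth histogram", {
  set.seed(83)
  n <- 800
  tab <- tibble::tibble(xi = c(rnorm(n, 40, 4), rnorm(n, 110, 4)) %% 180)
  h <- xi_polar_histogram(tab, bin_deg = 5)
  top <- h$xi_mid[order(h$n, decreasing = TRUE)][1:2]
  expect_equal(abs(fold90(diff(top))), 70, tolerance = 6)
})

test_that("profiles are invariant under row permutation", {
  set.seed(84)
  tab <- tibble::tibble(x_nm = runif(500, -400, 400),
                        y_nm = runif(500, -400, 400),
                        xi = runif(500, 0, 180), eta = runif(500, 0, 90))
  roi <- roi_spec(0, 0, 500)
  p1 <- radiality_profile(tab, roi)
  p2 <- radiality_profile(tab[sample.int(500), ], roi)
  expect_equal(p1, p2)
})

test_that("ground-truth matching joins on position within tolerance", {
  truth <- tibble::tibble(id = 1:3, frame = 1L,
                          x_nm = c(1000, 2000, 3000), y_nm = c(1000, 2000, 3000),
                          eta = c(10, 50, 80), xi = c(0, 60, 120),
                          delta = 100, photons = 5000)
  tab <- tibble::tibble(frame = 1L, x_nm = c(1010, 2950), y_nm = c(995, 3040),
                        eta = c(12, 78))
  m <- match_ground_truth(tab, truth, max_dist_nm = 100)
  expect_equal(m$id, c(1L, 3L))
  expect_equal(m$eta_true, c(10, 80))
})
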