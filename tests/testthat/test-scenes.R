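test_that("scene generation is deterministic given the seed", {
  a <- make_scene_random_orientations(10, 3, seed = 7)
  b <- make_scene_random_orientations(10, 3, seed = 7)
  expect_identical(tibble::as_tibble(a), tibble::as_tibble(b))
  c_ <- make_scene_random_orientations(10, 3, seed = 8)
  expect_false(identical(a$x_px, c_$x_px))
})

test_that("mean directions are area-uniform on the hemisphere", {
  sc <- make_scene_random_orientations(20000, 1, frame_size = 2000,
                                       min_sep_px = 0, edge_px = 1, seed = 9)
  ks <- suppressWarnings(stats::ks.test(cos(sc$eta * pi / 180), "punif"))
  expect_gt(ks$p.value, 0.01)
  ks2 <- suppressWarnings(stats::ks.test(sc$xi / 180, "punif"))
  expect_gt(ks2$p.value, 0.01)
})

test_that("the separation constraint is honoured or fails loudly", {
  sc <- make_scene_random_orientations(10, 2, frame_size = 64, seed = 10)
  for (fr in 1:2) {
    p <- as.matrix(sc[sc$frame == fr, c("x_px", "y_px")])
    d <- as.matrix(stats::dist(p))
    diag(d) <- Inf
    expect_gte(min(d), 8)
  }
  expect_error(make_scene_random_orientations(50, 1, frame_size = 24),
               "packing")
})

test_that("sphere-membrane labels follow the surface normal", {
  sc_bot <- make_scene_sphere_membrane(1500, plane_heights_nm = 1,
                                       n_per_plane = 50, seed = 11)
  expect_lt(max(sc_bot$eta), 3)
  sc_eq <- make_scene_sphere_membrane(1500, plane_heights_nm = 1500,
                                      n_per_plane = 50, frame_size = 64,
                                      seed = 12)
  expect_gt(min(sc_eq$eta), 87)
  # azimuth points radially away from the sphere-center image
  cen <- (64 - 1) / 2 * 130
  radial <- (atan2(sc_eq$y_px * 130 - cen, sc_eq$x_px * 130 - cen) *
               180 / pi) %% 180
  expect_lt(max(abs(fold90(sc_eq$xi - radial))), 1)
  expect_error(make_scene_sphere_membrane(1000, plane_heights_nm = 1200),
               "geometry")
})

test_that("polar angle increases from sphere bottom to equator", {
  sc <- make_scene_sphere_membrane(1500, n_per_plane = 80, seed = 13)
  prof <- tapply(sc$eta, sc$plane, mean)
  expect_true(all(diff(prof) > 0))
})

test_that("filament labels sit at the offset angle from the axis", {
  seg_h <- tibble::tibble(x0 = 500, y0 = 3000, x1 = 7000, y1 = 3000)
  sc <- make_scene_filaments(seg_h, label_offset_deg = 0, wobble = 0,
                             density_per_um = 40, seed = 14)
  expect_lt(max(abs(fold90(sc$xi - 0))), 1e-6)
  # a vertical filament with a 20-degree anchor gives eta near 20
  seg_v <- tibble::tibble(x0 = 3000, y0 = 3000, z0 = 0,
                          x1 = 3000, y1 = 3000.01, z1 = 8000)
  sc_v <- make_scene_filaments(seg_v, label_offset_deg = 20,
                               density_per_um = 200, seed = 15)
  expect_equal(mean(sc_v$eta), 20, tolerance = 1.5)
  expect_error(make_scene_filaments(tibble::tibble()), "empty|columns")
})

test_that("crossing filament families produce a bimodal azimuth split by the crossing angle", {
  segs <- tibble::tibble(x0 = c(500, 500), y0 = c(1000, 6000),
                         x1 = c(7500, 6500), y1 = c(1000, 1200))
  # family 2 runs at about -35 deg; rotate so the families cross at 70 deg
  ang2 <- (atan2(1200 - 6000, 6500 - 500) * 180 / pi) %% 180
  sc <- make_scene_filaments(segs, label_offset_deg = 0, wobble = 0,
                             density_per_um = 60, seed = 16)
  mod1 <- sc$xi[sc$filament == 1]
  mod2 <- sc$xi[sc$filament == 2]
  expect_lt(stats::sd(mod1), 1e-6)
  expect_equal(abs(fold90(mean(mod2) - mean(mod1))), abs(fold90(ang2)),
               tolerance = 1)
})

test_that("rendering without noise is exact and with noise is Poisson", {
  bank <- test_bank()
  sc <- make_scene_random_orientations(3, 1, seed = 17)
  clean <- render_stack(sc, noise = noise_model(background = 0,
                                                poisson = FALSE),
                        bank = bank)
  clean2 <- render_stack(sc, noise = noise_model(background = 0,
                                                 poisson = FALSE),
                         bank = bank)
  expect_identical(clean$frames, clean2$frames)
  # empty scene: background statistics are Poisson(10)
  sc0 <- make_scene_random_orientations(1, 1, photons = 1, seed = 18)
  sc0 <- sc0[0, ]
  attr(sc0, "frame_size_px") <- 64; attr(sc0, "n_frames") <- 1L
  class(sc0) <- c("fp_scene", class(tibble::tibble()))
  stk <- render_stack(sc0, noise = noise_model(background = 10), bank = bank,
                      seed = 19)
  expect_equal(mean(stk$frames), 10, tolerance = 0.1)
  expect_equal(stats::var(as.vector(stk$frames)), 10, tolerance = 0.3)
})

test_that("photon bookkeeping matches the per-molecule collection factors", {
  bank <- test_bank()
  sc <- make_scene_random_orientations(6, 2, photons = 8000, seed = 20)
  stk <- render_stack(sc, noise = noise_model(background = 0,
                                              poisson = FALSE), bank = bank)
  total <- sum(stk$frames)
  expected <- sum(sapply(seq_len(nrow(sc)), function(i) {
    m <- moments_from_orientation(sc$eta[i], sc$xi[i], sc$delta[i])
    8000 * sum(bank$K_window %*% m) / sum(bank$q * m)
  }))
  expect_equal(total, expected, tolerance = 0.005)
})

test_that("stacks round-trip through multi-page TIFF bit-exactly", {
  bank <- test_bank()
  sc <- make_scene_random_orientations(4, 3, seed = 21)
  stk <- render_stack(sc, noise = noise_model(background = 10), bank = bank,
                      seed = 22)
  p <- withr::local_tempfile(fileext = ".tif")
  write_stack_tiff(stk, p)
  rd <- read_stack(p)
  expect_equal(rd$n_frames, 3)
  for (fr in 1:3) {
    chans <- rd$get_frame(fr)
    ref <- fourpolar:::extract_channels(stk$frames[, , fr], stk$layout)
    for (ch in names(ref)) expect_equal(chans[[ch]], ref[[ch]],
                                        tolerance = 1e-6)
  }
  expect_error(rd$get_frame(10), "range")
})

test_that("quadrant layouts must tile without overlap", {
  lay <- quadrant_layout(64)
  expect_silent(fourpolar:::validate_layout(lay, c(128, 128)))
  bad <- lay; bad$x0[2] <- 10
  expect_error(fourpolar:::validate_layout(bad, c(128, 128)), "overlap")
  expect_error(fourpolar:::validate_layout(lay, c(100, 128)), "exceed")
})
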