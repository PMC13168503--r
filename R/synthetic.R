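# run code with a locally seeded RNG, restoring the caller's RNG state
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

new_scene <- function(truth, frame_size_px, n_frames, kind, seed = NULL) {
  stopifnot(all(truth$eta >= 0 & truth$eta <= 90),
            all(truth$delta >= 0 & truth$delta <= 180),
            all(truth$photons > 0))
  structure(truth,
            frame_size_px = frame_size_px, n_frames = n_frames,
            kind = kind, seed = seed,
            class = c("fp_scene", class(truth)))
}

#' Scene of uniformly random molecular orientations
#'
#' Ground-truth scene matching the Monte-Carlo validation conditions: mean
#' directions uniform over the upper hemisphere (area-uniform, i.e. `cos eta`
#' uniform on \[0, 1\] and `xi` uniform on \[0, 180)), fixed wobble, positions
#' uniform over the usable frame area with a minimum in-frame separation.
#'
#' @param n_molecules Molecules per frame.
#' @param n_frames Number of frames.
#' @param delta_fixed Wobble full apex angle (degrees) shared by all molecules.
#' @param photons Photons per molecule (at the open objective, before the
#'   split and NA reduction).
#' @param frame_size Frame width per channel, pixels.
#' @param min_sep_px Minimum separation between molecules within a frame.
#' @param edge_px Margin kept free at the frame edge.
#' @param seed RNG seed (scenes are reproducible given the seed).
#' @return An `fp_scene` tibble: `id, frame, x_px, y_px, x_nm, y_nm, eta, xi,
#'   delta, photons` (positions in pixels are 0-based; nm positions use a
#'   130 nm pixel unless a config is attached later at render time).
#' @export
make_scene_random_orientations <- function(n_molecules, n_frames = 1,
                                           delta_fixed = 100, photons = 5000,
                                           frame_size = 64, min_sep_px = 8,
                                           edge_px = 6, seed = NULL) {
  stopifnot(n_molecules > 0, n_frames > 0, photons > 0)
  lo <- edge_px; hi <- frame_size - 1 - edge_px
  if (hi - lo < min_sep_px && n_molecules > 1) {
    stop("packing error: frame too small for the separation constraint",
         call. = FALSE)
  }
  with_seed(seed, {
    frames <- purrr::map_dfr(seq_len(n_frames), function(fr) {
      pos <- matrix(NA_real_, 0, 2)
      tries <- 0
      while (nrow(pos) < n_molecules) {
        cand <- stats::runif(2, lo, hi)
        if (nrow(pos) == 0 ||
            min(sqrt(colSums((t(pos) - cand)^2))) >= min_sep_px) {
          pos <- rbind(pos, cand)
        }
        tries <- tries + 1
        if (tries > 2000 * n_molecules) {
          stop("packing error: could not satisfy the separation constraint",
               call. = FALSE)
        }
      }
      tibble::tibble(frame = fr, x_px = pos[, 1], y_px = pos[, 2])
    })
    n <- nrow(frames)
    truth <- dplyr::mutate(frames,
      id = dplyr::row_number(),
      eta = acos(stats::runif(n)) * 180 / pi,
      xi = stats::runif(n, 0, 180),
      delta = delta_fixed,
      photons = photons)
    new_scene(dplyr::select(truth, "id", "frame", "x_px", "y_px",
                            "eta", "xi", "delta", "photons"),
              frame_size, n_frames, "random_orientations", seed)
  })
}

#' Scene of normal-anchored labels on a membrane-coated sphere
#'
#' Molecules on horizontal circles of a sphere (membrane planes imaged at
#' different heights), with the mean dipole along the local outward normal,
#' optionally tilted by a fixed angle with uniformly random tilt azimuth.
#' The polar angle of the normal grows from 0 at the sphere bottom to 90 at
#' the equator, and its azimuth points radially away from the sphere center.
#'
#' @param radius_nm Sphere radius.
#' @param plane_heights_nm Heights of the imaged planes above the sphere
#'   bottom (all must be <= `radius_nm`).
#' @param label_tilt_deg Fixed tilt of the dipole away from the normal.
#' @param wobble Wobble full apex angle (degrees).
#' @param n_per_plane Molecules per plane.
#' @param photons Photons per molecule.
#' @param frame_size Frame width (pixels); sphere centered in the frame.
#' @param pixel_nm Object-plane pixel size.
#' @param seed RNG seed.
#' @return An `fp_scene` tibble with an extra `plane` column and
#'   `d_center_nm`, the lateral distance to the sphere-center image.
#' @export
make_scene_sphere_membrane <- function(radius_nm = 1500,
                                       plane_heights_nm = seq(100, 1400,
                                                              length.out = 5),
                                       label_tilt_deg = 0, wobble = 100,
                                       n_per_plane = 200, photons = 5000,
                                       frame_size = 64, pixel_nm = 130,
                                       seed = NULL) {
  stopifnot(radius_nm > 0)
  if (any(plane_heights_nm > radius_nm + 1e-9)) {
    stop("geometry error: plane height above the sphere equator", call. = FALSE)
  }
  cen <- (frame_size - 1) / 2 * pixel_nm
  with_seed(seed, {
    truth <- purrr::map_dfr(seq_along(plane_heights_nm), function(pi_) {
      h <- plane_heights_nm[pi_]
      polar <- acos(pmin(1, (radius_nm - h) / radius_nm))  # normal polar angle
      r_lat <- radius_nm * sin(polar)
      phi <- stats::runif(n_per_plane, 0, 2 * pi)
      nrm <- cbind(sin(polar) * cos(phi), sin(polar) * sin(phi),
                   rep(cos(polar), n_per_plane))
      dip <- tilt_directions(nrm, label_tilt_deg)
      ang <- direction_to_angles(dip)
      tibble::tibble(plane = pi_, frame = 1L,
                     x_px = (cen + r_lat * cos(phi)) / pixel_nm,
                     y_px = (cen + r_lat * sin(phi)) / pixel_nm,
                     d_center_nm = r_lat,
                     eta = ang$eta, xi = ang$xi,
                     delta = wobble, photons = photons)
    })
    truth$id <- seq_len(nrow(truth))
    new_scene(truth, frame_size, 1L, "sphere_membrane", seed)
  })
}

#' Scene of labelled filaments
#'
#' Molecules distributed along 3D line segments with the mean dipole at a
#' fixed offset angle from the local filament axis (uniformly random azimuth
#' about the axis), emulating dye anchorage to actin filaments.
#'
#' @param segments Tibble/data frame with columns `x0, y0, z0, x1, y1, z1`
#'   (nm; z is only used for the filament direction) and optionally `id`.
#' @param label_offset_deg Offset of the dipole from the filament axis.
#' @param wobble Wobble full apex angle (degrees).
#' @param density_per_um Mean labelling density along the filament.
#' @param photons Photons per molecule.
#' @param frame_size,pixel_nm Frame geometry.
#' @param n_frames Molecules are spread uniformly over this many frames.
#' @param seed RNG seed.
#' @return An `fp_scene` tibble with a `filament` column.
#' @export
make_scene_filaments <- function(segments, label_offset_deg = 20, wobble = 100,
                                 density_per_um = 30, photons = 5000,
                                 frame_size = 64, pixel_nm = 130,
                                 n_frames = 1, seed = NULL) {
  segments <- tibble::as_tibble(segments)
  if (nrow(segments) == 0) stop("empty segment list", call. = FALSE)
  if (!all(c("x0", "y0", "x1", "y1") %in% names(segments))) {
    stop("segments need columns x0, y0, x1, y1 (and optionally z0, z1)",
         call. = FALSE)
  }
  if (!"z0" %in% names(segments)) segments$z0 <- 0
  if (!"z1" %in% names(segments)) segments$z1 <- 0
  if (!"id" %in% names(segments)) segments$id <- seq_len(nrow(segments))
  lim <- (frame_size - 1) * pixel_nm
  if (any(pmin(segments$x0, segments$x1) < 0) ||
      any(pmax(segments$x0, segments$x1) > lim) ||
      any(pmin(segments$y0, segments$y1) < 0) ||
      any(pmax(segments$y0, segments$y1) > lim)) {
    stop("segments must lie inside the frame", call. = FALSE)
  }
  with_seed(seed, {
    truth <- purrr::map_dfr(seq_len(nrow(segments)), function(si) {
      s <- segments[si, ]
      v <- c(s$x1 - s$x0, s$y1 - s$y0, s$z1 - s$z0)
      len <- sqrt(sum(v^2))
      n <- stats::rpois(1, density_per_um * len / 1000)
      if (n == 0) return(NULL)
      t_ <- stats::runif(n)
      axis <- matrix(v / len, n, 3, byrow = TRUE)
      dip <- tilt_directions(axis, label_offset_deg)
      ang <- direction_to_angles(dip)
      tibble::tibble(filament = s$id,
                     frame = sample.int(n_frames, n, replace = TRUE),
                     x_px = (s$x0 + t_ * v[1]) / pixel_nm,
                     y_px = (s$y0 + t_ * v[2]) / pixel_nm,
                     eta = ang$eta, xi = ang$xi,
                     delta = wobble, photons = photons)
    })
    if (is.null(truth) || nrow(truth) == 0) {
      stop("no molecules generated; increase density_per_um", call. = FALSE)
    }
    truth$id <- seq_len(nrow(truth))
    new_scene(truth, frame_size, n_frames, "filaments", seed)
  })
}

# rotate unit vectors away from themselves by a fixed angle, random azimuth
tilt_directions <- function(axis, tilt_deg) {
  n <- nrow(axis)
  if (tilt_deg == 0) return(axis)
  t_ <- tilt_deg * pi / 180
  phi <- stats::runif(n, 0, 2 * pi)
  ref <- matrix(rep(c(0, 0, 1), n), n, 3, byrow = TRUE)
  swap <- abs(axis[, 3]) > 0.9
  ref[swap, ] <- matrix(rep(c(1, 0, 0), sum(swap)), sum(swap), 3, byrow = TRUE)
  e1 <- ref - axis * rowSums(ref * axis)
  e1 <- e1 / sqrt(rowSums(e1^2))
  e2 <- cbind(axis[, 2] * e1[, 3] - axis[, 3] * e1[, 2],
              axis[, 3] * e1[, 1] - axis[, 1] * e1[, 3],
              axis[, 1] * e1[, 2] - axis[, 2] * e1[, 1])
  cos(t_) * axis + sin(t_) * (cos(phi) * e1 + sin(phi) * e2)
}

# unit direction -> (eta, xi) with the upper-hemisphere/180-degree conventions
direction_to_angles <- function(u) {
  flip <- u[, 3] < 0
  u[flip, ] <- -u[flip, ]
  eta <- acos(pmin(1, pmax(-1, u[, 3]))) * 180 / pi
  xi <- (atan2(u[, 2], u[, 1]) * 180 / pi) %% 180
  list(eta = eta, xi = xi)
}

#' Noise model of the camera
#'
#' @param background Background photons per pixel per channel.
#' @param read_noise_sd Gaussian read noise (photons RMS), 0 to disable.
#' @param gain Camera gain (counts per photon).
#' @param poisson Apply Poisson shot noise?
#' @return A `noise_model` object.
#' @export
noise_model <- function(background = 10, read_noise_sd = 0, gain = 1,
                        poisson = TRUE) {
  stopifnot(background >= 0, read_noise_sd >= 0, gain > 0)
  structure(list(background = background, read_noise_sd = read_noise_sd,
                 gain = gain, poisson = poisson), class = "noise_model")
}

#' Zernike/defocus aberration specification
#'
#' @param zernike Named numeric vector of Noll-indexed Zernike coefficients
#'   (radians RMS), e.g. `c("5" = 0.3)` for oblique astigmatism.
#' @param z1 Defocus in nm (added to the configuration's `z1`).
#' @return An `aberration_spec` object.
#' @export
aberration_spec <- function(zernike = numeric(), z1 = 0) {
  stopifnot(all(is.finite(zernike)), is.finite(z1))
  structure(list(zernike = zernike, z1 = z1), class = "aberration_spec")
}

#' Render a four-channel camera stack from a scene
#'
#' For every molecule: second moments from its orientation, polarized PSFs
#' from the moment basis (optionally with pupil aberrations), placement at
#' its (sub-pixel, quantized) position; then background, Poisson shot noise
#' and optional Gaussian read noise per channel; channels are tiled as
#' quadrants of one camera frame.
#'
#' @param scene An `fp_scene`.
#' @param config An [optical_config()] (ignored if `bank` given).
#' @param noise A [noise_model()].
#' @param aberration Optional [aberration_spec()].
#' @param bank Optional prebuilt [psf_bank()].
#' @param seed RNG seed for the noise.
#' @return A list of class `fp_stack`: `frames` (array
#'   `2*frame_size x 2*frame_size x n_frames`), `layout` (quadrant layout),
#'   `truth` (ground-truth tibble with rendered positions in px and nm),
#'   `config`, `noise`, `seed`.
#' @export
render_stack <- function(scene, config = optical_config(),
                         noise = noise_model(), aberration = NULL,
                         bank = NULL, seed = NULL) {
  stopifnot(inherits(scene, "fp_scene"))
  if (is.null(bank)) bank <- psf_bank(config, aberration = aberration)
  config <- bank$config
  F <- attr(scene, "frame_size_px")
  nfr <- attr(scene, "n_frames")
  layout <- quadrant_layout(F)
  px <- config$pixel_size_obj
  frames <- array(0, dim = c(2L * F, 2L * F, nfr))
  truth <- tibble::as_tibble(scene)
  truth$x_render_px <- NA_real_; truth$y_render_px <- NA_real_
  for (fr in seq_len(nfr)) {
    sub <- which(truth$frame == fr)
    imgs <- lapply(CHANNELS, function(ch) matrix(0, F, F))
    names(imgs) <- CHANNELS
    for (i in sub) {
      m <- moments_from_orientation(truth$eta[i], truth$xi[i], truth$delta[i],
                                    all_six = TRUE)
      one <- psf_from_moments(m, truth$photons[i], bank,
                              position = c(truth$x_px[i], truth$y_px[i]),
                              frame_size = F)
      for (ch in CHANNELS) imgs[[ch]] <- imgs[[ch]] + one[[ch]]
      truth$x_render_px[i] <- attr(one, "position")[1]
      truth$y_render_px[i] <- attr(one, "position")[2]
    }
    for (ch in CHANNELS) {
      q <- layout[layout$channel == ch, ]
      frames[q$x0 + seq_len(F), q$y0 + seq_len(F), fr] <- imgs[[ch]]
    }
  }
  frames <- frames + noise$background
  with_seed(seed, {
    if (noise$poisson) {
      frames[] <- stats::rpois(length(frames), frames)
    }
    if (noise$read_noise_sd > 0) {
      frames[] <- frames + stats::rnorm(length(frames), 0, noise$read_noise_sd)
    }
  })
  frames <- frames * noise$gain
  truth$x_nm <- truth$x_render_px * px
  truth$y_nm <- truth$y_render_px * px
  structure(list(frames = frames, layout = layout, truth = truth,
                 config = config, noise = noise, seed = seed,
                 frame_size_px = F),
            class = "fp_stack")
}

#' @export
print.fp_stack <- function(x, ...) {
  cat(sprintf("<fp_stack> %d frame(s) of %dx%d (4 quadrants of %d px), %d molecules\n",
              dim(x$frames)[3], dim(x$frames)[1], dim(x$frames)[2],
              x$frame_size_px, nrow(x$truth)))
  invisible(x)
}
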