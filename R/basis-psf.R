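# analyzer angles (degrees) of the four channels
CHANNEL_ANALYZER <- c(I0 = 0, I90 = 90, I45 = 45, I135 = 135)

# block-bin a matrix by os x os area integration
bin_block <- function(M, os) {
  n1 <- nrow(M) %/% os; n2 <- ncol(M) %/% os
  tmp <- rowsum(M, rep(seq_len(n1), each = os))
  t(rowsum(t(tmp), rep(seq_len(n2), each = os)))
}

#' Precomputed rendering bank of polarized basis point-spread functions
#'
#' Computes, once per optical configuration, everything the renderer and the
#' pipeline need: the six moment-basis PSF images of every channel, area-binned
#' to the camera pixel grid at each of `oversample^2` sub-pixel phases; the
#' integrated propagation matrix `K` (channels x accessible moments, by
#' pupil-plane Parseval quadrature, i.e. the full-plane image integrals); the
#' full-aperture normalization vector `q` such that `q . m` is the power an
#' emitter with moments `m` delivers through the open objective; and the
#' per-channel Gaussian-equivalent PSF radii used as fixed detection radii.
#'
#' The sub-pixel position of a rendered molecule is quantized to
#' `pixel_size_obj / oversample` (16.25 nm at defaults); the ground truth
#' tables report the actually rendered position.
#'
#' @param config An [optical_config()].
#' @param oversample Sub-pixel phases per axis (rendering resolution).
#' @param window_px Odd patch width in camera pixels.
#' @param aberration Optional [aberration_spec()]: a Zernike phase applied
#'   identically to both arms (unpolarized aberration) plus extra defocus.
#' @return An object of class `psf_bank`.
#' @export
psf_bank <- function(config = optical_config(), oversample = 8, window_px = 15,
                     aberration = NULL) {
  validate_optical_config(config)
  stopifnot(window_px %% 2 == 1, oversample >= 1)
  if (!is.null(aberration)) {
    stopifnot(inherits(aberration, "aberration_spec"))
    config$z1 <- config$z1 + aberration$z1
  }
  os <- as.integer(oversample); W <- as.integer(window_px)
  n <- config$pupil_samples
  lam <- config$wavelength_em
  dxs <- config$pixel_size_obj / os
  Ns <- (W + 2L) * os                       # oversampled grid incl. shift margin
  # half-sample offset so each pixel's os samples sit symmetrically about
  # the pixel center (otherwise every render is biased by dxs/2)
  xs <- (seq_len(Ns) - 1 - (Ns %/% 2) + 0.5) * dxs
  u1 <- seq(-config$NA_obj, config$NA_obj, length.out = n)
  du <- u1[2] - u1[1]
  Mdft <- exp(2i * pi * outer(xs, u1) / lam)   # Ns x n

  # unpolarized pupil aberration phase (shared by both arms)
  ab_phase <- 1
  if (!is.null(aberration) && length(aberration$zernike) > 0) {
    ux <- matrix(u1, n, n); uy <- matrix(u1, n, n, byrow = TRUE)
    rho <- sqrt(ux^2 + uy^2) / config$NA_obj
    th <- atan2(uy, ux)
    phi <- matrix(0, n, n)
    for (jn in names(aberration$zernike)) {
      phi <- phi + aberration$zernike[[jn]] *
        zernike_noll(as.integer(jn), pmin(rho, 1), th)
    }
    ab_phase <- exp(1i * phi)
  }

  arms <- list(low = config$NA_low, high = config$NA_high)
  # scalar image amplitudes a[[channel]][[axis]] (Ns x Ns complex)
  amp <- list()
  pupil_prod <- list()                       # pupil-side integrals per channel
  for (ch in CHANNELS) {
    arm <- config$channel_arms[[ch]]
    alpha <- CHANNEL_ANALYZER[[ch]] * pi / 180
    f <- lapply(c("x", "y", "z"), function(ax)
      build_pupil_field(ax, config, NA_mask = arms[[arm]]))
    names(f) <- c("x", "y", "z")
    S <- lapply(f, function(pf) cos(alpha) * pf$Ex + sin(alpha) * pf$Ey)
    # 50/50 splitter: half the field energy per arm; shared aberration phase
    S <- lapply(S, function(s) s * ab_phase / sqrt(2))
    amp[[ch]] <- lapply(S, function(s) (du^2 / lam^2) * (Mdft %*% s %*% t(Mdft)))
    pupil_prod[[ch]] <- sapply(moment_pairs(), function(p)
      sum(Re(S[[p[1]]] * Conj(S[[p[2]]]))) * du^2 / lam^2 * ifelse(p[1] == p[2], 1, 2))
  }

  # integrated propagation matrix over the accessible moments
  K <- t(sapply(CHANNELS, function(ch) pupil_prod[[ch]][1:4]))
  dimnames(K) <- list(CHANNELS, MOMENTS)
  if (!is.finite(kappa(K)) || kappa(K) > 1e8) {
    stop("calibration degeneracy: theoretical K matrix is not invertible",
         call. = FALSE)
  }

  # full-objective normalization vector q (no analyzer, both components)
  fobj <- lapply(c("x", "y", "z"), function(ax) build_pupil_field(ax, config))
  names(fobj) <- c("x", "y", "z")
  qv <- sapply(moment_pairs()[1:4], function(p)
    sum(Re(fobj[[p[1]]]$Ex * Conj(fobj[[p[2]]]$Ex) +
           fobj[[p[1]]]$Ey * Conj(fobj[[p[2]]]$Ey))) * du^2 / lam^2 *
      ifelse(p[1] == p[2], 1, 2))
  names(qv) <- MOMENTS

  # oversampled basis images and phase-resolved binned patches
  k0 <- Ns %/% 2                             # 0-based index of the center sample
  hw <- (W - 1L) %/% 2
  patches <- array(0, dim = c(W, W, 6L, 4L, os, os),
                   dimnames = list(NULL, NULL, MOMENTS6, CHANNELS, NULL, NULL))
  shifts <- seq_len(os) - 1L - (os %/% 2L)   # sub-pixel shift in samples
  for (ci in seq_along(CHANNELS)) {
    a <- amp[[CHANNELS[ci]]]
    for (ji in seq_along(MOMENTS6)) {
      p <- moment_pairs()[[ji]]
      B <- Re(a[[p[1]]] * Conj(a[[p[2]]])) * ifelse(p[1] == p[2], 1, 2) * dxs^2
      for (qx in seq_len(os)) for (qy in seq_len(os)) {
        # shifting the sampling window by -q samples places the PSF at +q
        ix <- k0 - shifts[qx] - hw * os - os %/% 2L + seq_len(W * os)
        iy <- k0 - shifts[qy] - hw * os - os %/% 2L + seq_len(W * os)
        patches[, , ji, ci, qx, qy] <- bin_block(B[ix, iy], os)
      }
    }
  }

  # Gaussian-equivalent radius per channel (isotropic emitter), in pixels:
  # intensity-weighted second moment over the central 7x7 px
  cphase <- os %/% 2L + 1L
  sigma_px <- sapply(seq_along(CHANNELS), function(ci) {
    img <- patches[, , "xx", ci, cphase, cphase] +
           patches[, , "yy", ci, cphase, cphase] +
           patches[, , "zz", ci, cphase, cphase]
    cc <- hw + 1L; sel <- (cc - 3L):(cc + 3L)
    img <- img[sel, sel]
    xg <- matrix(-3:3, 7, 7); yg <- t(xg)
    sqrt(0.5 * (sum(img * xg^2) + sum(img * yg^2)) / sum(img))
  })
  names(sigma_px) <- CHANNELS

  structure(list(config = config, oversample = os, window_px = W,
                 patches = patches, K = K, q = qv, sigma_px = sigma_px,
                 K_window = patch_K(patches, os)),
            class = "psf_bank")
}

#' Zernike polynomial by Noll index
#'
#' Standard Noll-ordered Zernike polynomial on the unit pupil, with the usual
#' RMS normalization (so a coefficient is the RMS phase in radians).
#'
#' @param j Noll index (>= 1).
#' @param rho Radial coordinate(s) in \[0, 1\].
#' @param theta Azimuth(s) in radians.
#' @return Polynomial values, same shape as `rho`.
#' @export
zernike_noll <- function(j, rho, theta) {
  stopifnot(j >= 1)
  # Noll index -> (n, m)
  n <- 0
  while ((n + 1) * (n + 2) / 2 < j) n <- n + 1
  base <- n * (n + 1) / 2
  r <- j - base                  # 1..n+1
  ms <- sort(abs(seq(-n, n, by = 2)))
  m_abs <- ms[r]
  # Noll sign rule: even j -> cosine (m >= 0), odd j -> sine (m < 0)
  use_sin <- (j %% 2 == 1) && m_abs > 0
  R <- 0
  for (k in 0:((n - m_abs) / 2)) {
    R <- R + (-1)^k * factorial(n - k) /
      (factorial(k) * factorial((n + m_abs) / 2 - k) *
         factorial((n - m_abs) / 2 - k)) * rho^(n - 2 * k)
  }
  norm <- if (m_abs == 0) sqrt(n + 1) else sqrt(2 * (n + 1))
  if (m_abs == 0) norm * R
  else if (use_sin) norm * R * sin(m_abs * theta)
  else norm * R * cos(m_abs * theta)
}

moment_pairs <- function() {
  list(xx = c("x", "x"), yy = c("y", "y"), zz = c("z", "z"),
       xy = c("x", "y"), xz = c("x", "z"), yz = c("y", "z"))
}

# window-integrated K (center phase): what a finite patch actually carries
patch_K <- function(patches, os) {
  cp <- os %/% 2L + 1L
  K <- sapply(1:4, function(j) sapply(1:4, function(ci)
    sum(patches[, , j, ci, cp, cp])))          # channels in rows
  dimnames(K) <- list(CHANNELS, MOMENTS)
  K
}

#' @export
print.psf_bank <- function(x, ...) {
  cat(sprintf("<psf_bank> window %d px, oversample %d, cond(K) = %.2f\n",
              x$window_px, x$oversample, kappa(x$K)))
  cat("  sigma_px:", paste(sprintf("%s=%.2f", names(x$sigma_px), x$sigma_px),
                           collapse = " "), "\n")
  invisible(x)
}

#' Basis PSF images and the integrated propagation matrix
#'
#' The four polarized channel intensities of a molecule with second-order
#' moments `m` are `I_c(r) = sum_j B_cj(r) m_j`.  This returns the centered
#' basis images `B_cj` on the camera pixel grid for all six moment components
#' (the `xz`/`yz` images integrate to zero, which is why only four moments are
#' accessible from integrated intensities) together with the integrated 4x4
#' matrix `K` over the accessible components and its condition number.
#'
#' @param config An [optical_config()].
#' @param bank Optionally a prebuilt [psf_bank()] (avoids recomputation).
#' @return A list with `B` (array `window_px x window_px x 6 x 4`), `K`,
#'   `cond`, `q`, and the generating `config`.
#' @export
basis_psfs <- function(config = optical_config(), bank = NULL) {
  if (is.null(bank)) bank <- psf_bank(config)
  cp <- bank$oversample %/% 2L + 1L
  B <- bank$patches[, , , , cp, cp]
  list(B = B, K = bank$K, cond = kappa(bank$K), q = bank$q,
       config = bank$config)
}

#' Render noise-free polarized PSFs of one molecule
#'
#' Places the four-channel PSF of a molecule with moments `m` and total
#' photon count `photons` (defined before the channel split and NA reduction,
#' i.e. the photons the open objective would collect from this molecule) at a
#' continuous position on the camera grid.  The sub-pixel position is
#' quantized to the bank's rendering resolution.
#'
#' @param m Named moments (4 or 6 components; cross terms default to 0).
#' @param photons Total photon count at the open objective.
#' @param bank A [psf_bank()].
#' @param position Position `c(x, y)` in pixels (0-based, pixel centers at
#'   integers); defaults to the frame center.
#' @param frame_size Output frame width in pixels.
#' @return A named list of four `frame_size x frame_size` images, with
#'   attributes `position` (the rendered, quantization-snapped position) and
#'   `collection_factor` (the fraction of `photons` present in the four
#'   full-plane channel integrals).
#' @export
psf_from_moments <- function(m, photons, bank, position = NULL,
                             frame_size = bank$window_px) {
  stopifnot(inherits(bank, "psf_bank"), photons > 0)
  m6 <- stats::setNames(numeric(6), MOMENTS6)
  m <- unlist(m)
  if (is.null(names(m))) m6[seq_along(m)] <- m else m6[names(m)] <- m
  validate_moments(m6)
  if (is.null(position)) position <- rep((frame_size - 1) / 2, 2)
  if (any(position < 0) || any(position > frame_size - 1)) {
    stop("position outside the frame", call. = FALSE)
  }
  scale <- photons / sum(bank$q * m6[MOMENTS])
  pl <- place_patch_indices(position, bank, frame_size)
  out <- lapply(seq_along(CHANNELS), function(ci) {
    img <- matrix(0, frame_size, frame_size)
    patch <- matrix(0, bank$window_px, bank$window_px)
    for (j in which(m6 != 0)) {
      patch <- patch + m6[j] * bank$patches[, , j, ci, pl$qx, pl$qy]
    }
    img[pl$fx, pl$fy] <- patch[pl$px, pl$py] * scale
    img
  })
  names(out) <- CHANNELS
  attr(out, "position") <- pl$snapped
  attr(out, "collection_factor") <-
    sum(bank$K %*% m6[MOMENTS]) / sum(bank$q * m6[MOMENTS])
  out
}

# map a continuous 0-based pixel position to integer pixel + phase index and
# clipped frame/patch index ranges
place_patch_indices <- function(position, bank, frame_size) {
  os <- bank$oversample; W <- bank$window_px; hw <- (W - 1L) %/% 2L
  sub <- round(position * os) / os
  ipix <- floor(sub + 0.5)
  frac <- sub - ipix                          # in [-0.5, 0.5)
  q <- as.integer(round(frac * os)) + os %/% 2L + 1L
  q <- pmin(pmax(q, 1L), os)
  px_all <- (ipix[1] - hw):(ipix[1] + hw)
  py_all <- (ipix[2] - hw):(ipix[2] + hw)
  okx <- px_all >= 0 & px_all <= frame_size - 1
  oky <- py_all >= 0 & py_all <= frame_size - 1
  list(qx = q[1], qy = q[2],
       fx = px_all[okx] + 1L, fy = py_all[oky] + 1L,
       px = which(okx), py = which(oky),
       snapped = c((ipix[1] + (q[1] - 1 - os %/% 2L) / os),
                   (ipix[2] + (q[2] - 1 - os %/% 2L) / os)))
}

#' Export basis PSFs as a multi-page TIFF
#'
#' One page per channel/moment pair, for visual inspection.
#'
#' @param basis Result of [basis_psfs()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_basis_tiff <- function(basis, path) {
  pages <- list()
  for (ci in seq_along(CHANNELS)) for (j in seq_along(MOMENTS6)) {
    img <- basis$B[, , j, ci]
    rng <- max(abs(img)); if (rng == 0) rng <- 1
    pages[[length(pages) + 1L]] <- (img / rng + 1) / 2
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}
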