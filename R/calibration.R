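#' Measure the integrated calibration matrix from a nanobead series
#'
#' A linear polarizer rotated in the emission path of an unpolarized
#' (nanobead) emitter emulates an in-plane dipole with second moments
#' `(cos^2 t, sin^2 t, 0, sin t cos t)` at polarizer angle `t`, so every
#' channel intensity follows `a + b cos(2 (t - t_c))`:
#' the mean `a` gives `(K_xx + K_yy) / 2`, the cosine/sine quadratures give
#' `(K_xx - K_yy) / 2` and `K_xy / 2`.  The same bead without the polarizer
#' emulates the isotropic moments `(1/3, 1/3, 1/3, 0)`, identifying the
#' remaining `zz` column: `K_zz = 3 I_unpol - K_xx - K_yy`.  Without the
#' unpolarized frame the `zz` column is unidentifiable from in-plane states
#' and an error is raised.  Relative channel gains are absorbed row-wise and
#' cancel in orientation retrieval.
#'
#' @param polarizer_series Tibble with columns `angle_deg, I0, I90, I45, I135`
#'   (one row per polarizer angle; >= 8 angles spanning >= 180 degrees).
#' @param unpolarized_frame Named intensities (I0, I90, I45, I135) of the
#'   bead without the polarizer.
#' @param min_r2 Minimum sinusoid-fit R-squared per channel.
#' @return An `fp_calibration` object: the 4x4 matrix `K`, per-entry standard
#'   errors, condition number, per-channel fit R-squared, provenance.
#' @export
calibrate_K <- function(polarizer_series, unpolarized_frame = NULL,
                        min_r2 = 0.9) {
  s <- tibble::as_tibble(polarizer_series)
  stopifnot(all(c("angle_deg", CHANNELS) %in% names(s)))
  if (nrow(s) < 8) stop("need at least 8 polarizer angles", call. = FALSE)
  if (diff(range(s$angle_deg)) < 180 - 1e-9) {
    stop("polarizer angles must span at least 180 degrees", call. = FALSE)
  }
  if (is.null(unpolarized_frame)) {
    stop(paste("calibration degeneracy: the zz column cannot be identified",
               "from in-plane polarizer states alone; supply the",
               "unpolarized bead frame"), call. = FALSE)
  }
  up <- unlist(unpolarized_frame)[CHANNELS]
  t2 <- 2 * s$angle_deg * pi / 180
  K <- matrix(0, 4, 4, dimnames = list(CHANNELS, MOMENTS))
  SE <- K
  r2 <- stats::setNames(numeric(4), CHANNELS)
  for (ch in CHANNELS) {
    fit <- stats::lm(s[[ch]] ~ cos(t2) + sin(t2))
    cf <- stats::coef(fit)
    # vcov warns on noise-free series ("essentially perfect fit")
    se <- suppressWarnings(sqrt(diag(stats::vcov(fit))))
    tss <- sum((s[[ch]] - mean(s[[ch]]))^2)
    r2[ch] <- if (tss > 0) 1 - sum(stats::residuals(fit)^2) / tss else 1
    K[ch, "xx"] <- cf[1] + cf[2]
    K[ch, "yy"] <- cf[1] - cf[2]
    K[ch, "xy"] <- 2 * cf[3]
    K[ch, "zz"] <- 3 * up[[ch]] - K[ch, "xx"] - K[ch, "yy"]
    SE[ch, "xx"] <- sqrt(se[1]^2 + se[2]^2)
    SE[ch, "yy"] <- sqrt(se[1]^2 + se[2]^2)
    SE[ch, "xy"] <- 2 * se[3]
    SE[ch, "zz"] <- sqrt(9 * (se[1]^2 / nrow(s)) + SE[ch, "xx"]^2)
  }
  if (any(r2 < min_r2)) {
    stop(sprintf("calibration quality: sinusoid fit R^2 below %.2f in %s",
                 min_r2, paste(CHANNELS[r2 < min_r2], collapse = ", ")),
         call. = FALSE)
  }
  if (!is.finite(kappa(K)) || kappa(K) > 1e8) {
    stop("calibration degeneracy: measured K is singular", call. = FALSE)
  }
  structure(list(K = K, se = SE, cond = kappa(K), r2 = r2,
                 provenance = "measured"),
            class = "fp_calibration")
}

#' Theoretical calibration from the forward model
#' @param bank A [psf_bank()].
#' @return An `fp_calibration` with provenance `"theory"`.
#' @export
theory_calibration <- function(bank) {
  structure(list(K = bank$K, se = bank$K * 0, cond = kappa(bank$K),
                 r2 = stats::setNames(rep(NA_real_, 4), CHANNELS),
                 provenance = "theory", q = bank$q, scale = 1),
            class = "fp_calibration")
}

#' @export
print.fp_calibration <- function(x, ...) {
  cat(sprintf("<fp_calibration> provenance: %s, cond(K) = %.2f\n",
              x$provenance, x$cond))
  print(signif(x$K, 4))
  invisible(x)
}

#' @export
tidy.fp_calibration <- function(x, ...) {
  tibble::tibble(
    channel = rep(CHANNELS, times = 4),
    moment = rep(MOMENTS, each = 4),
    estimate = as.vector(x$K),
    std.error = as.vector(x$se))
}

#' @export
glance.fp_calibration <- function(x, ...) {
  tibble::tibble(provenance = x$provenance, cond = x$cond,
                 min_r2 = suppressWarnings(min(x$r2)))
}

#' Write / read a calibration as JSON
#' @param cal An `fp_calibration`.
#' @param path File path.
#' @return `path` (write) or the calibration (read).
#' @export
write_calibration <- function(cal, path) {
  jsonlite::write_json(list(K = cal$K, se = cal$se, cond = cal$cond,
                            r2 = as.list(cal$r2), provenance = cal$provenance),
                       path, digits = NA, auto_unbox = TRUE, matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  K <- matrix(as.numeric(j$K), 4, 4, dimnames = list(CHANNELS, MOMENTS))
  SE <- matrix(as.numeric(j$se), 4, 4, dimnames = list(CHANNELS, MOMENTS))
  structure(list(K = K, se = SE, cond = j$cond, r2 = unlist(j$r2),
                 provenance = j$provenance),
            class = "fp_calibration")
}

#' Estimator-matched synthetic calibration
#'
#' Emulates the nanobead + rotating-polarizer calibration protocol inside the
#' forward model: noise-free PSFs of fixed in-plane dipoles (the molecular
#' states a polarizer at angle `t` emulates, moments
#' `(cos^2 t, sin^2 t, 0, sin t cos t)`) and of an isotropic emitter are
#' rendered and measured with the same intensity estimator as the data, and
#' the resulting series is fed to [calibrate_K()].  The measured matrix
#' therefore absorbs the estimator's channel-dependent intensity recovery
#' (e.g. the different Gaussian-fit volume fractions of the low- and high-NA
#' arms), exactly as the instrument's bead calibration absorbs its channel
#' gains.
#'
#' @param bank A [psf_bank()].
#' @param estimator Intensity estimator, as in [fit_psf()].
#' @param photons Photon scale of the synthetic states (noise-free; scale
#'   cancels).
#' @param n_angles Number of polarizer angles over 180 degrees.
#' @param window Fitting window (pixels).
#' @return An `fp_calibration` with provenance `"synthetic"`.
#' @export
calibrate_K_estimator <- function(bank, estimator = "gauss_sym",
                                  photons = 1e5, n_angles = 12, window = 11) {
  F <- bank$window_px
  cen <- (F - 1) / 2
  # constant-brightness source: the photon count of each state scales with
  # the power its moments deliver through the open objective, as a real bead
  # behind a polarizer does (so the measured series is exactly linear in m)
  measure <- function(m6) {
    ph <- photons * sum(bank$q * m6[1:4]) / bank$q[[1]]
    img <- psf_from_moments(m6, ph, bank, position = c(cen, cen),
                            frame_size = F)
    sapply(CHANNELS, function(ch)
      fit_psf(img[[ch]], as.integer(cen), as.integer(cen), estimator,
              window = window,
              sigma_start = bank$sigma_px[[ch]])$intensity)
  }
  angles <- seq(0, 180, length.out = n_angles + 1)[seq_len(n_angles + 1)]
  series <- purrr::map_dfr(angles, function(th) {
    tr <- th * pi / 180
    I <- measure(c(xx = cos(tr)^2, yy = sin(tr)^2, zz = 0,
                   xy = sin(tr) * cos(tr)))
    tibble::as_tibble(as.list(I)) |>
      dplyr::mutate(angle_deg = th, .before = 1)
  })
  up <- measure(c(xx = 1 / 3, yy = 1 / 3, zz = 1 / 3, xy = 0))
  cal <- calibrate_K(series, up)
  cal$provenance <- "synthetic"
  cal$q <- bank$q
  cal$scale <- photons / bank$q[[1]]    # photon scale of the measured matrix
  cal
}

#' Estimator response surface over orientation space
#'
#' The finite-window Gaussian (or box) intensity estimators recover a
#' shape-dependent fraction of each channel's photons, and the in-plane +
#' isotropic calibration states of [calibrate_K_estimator()] cannot probe
#' every shape.  This maps the residual per-channel recovery factor
#' `g_c(eta, xi, delta) = I_fitted / I_modelled` on a grid by rendering
#' noise-free PSFs and measuring them with the estimator; the known-brightness
#' maximum-likelihood retrieval interpolates it to de-bias its forward model.
#'
#' @param bank A [psf_bank()].
#' @param cal The matching [calibrate_K_estimator()] calibration.
#' @param estimator Intensity estimator.
#' @param eta,xi,delta Grid axes (degrees); `xi` is treated as periodic
#'   modulo 180.
#' @param window Fitting window.
#' @return An `fp_response` object (grid axes + 4D array of factors).
#' @export
estimator_response <- function(bank, cal, estimator = "gauss_sym",
                               eta = seq(0, 90, by = 7.5),
                               xi = seq(0, 180, by = 30),
                               delta = seq(0, 180, by = 30),
                               window = 11) {
  F <- bank$window_px
  cen <- (F - 1) / 2
  g <- array(1, dim = c(length(eta), length(xi), length(delta), 4L))
  for (ie in seq_along(eta)) for (ix in seq_along(xi)) for (id in seq_along(delta)) {
    m6 <- moments_from_orientation(eta[ie], xi[ix], delta[id], all_six = TRUE)
    ph <- 1e5
    img <- psf_from_moments(m6, ph, bank, position = c(cen, cen),
                            frame_size = F)
    P <- as.vector(cal$K %*% m6[1:4]) / (cal$scale * sum(bank$q * m6[1:4])) * ph
    If <- vapply(CHANNELS, function(ch)
      fit_psf(img[[ch]], as.integer(cen), as.integer(cen), estimator,
              window = window, sigma_start = bank$sigma_px[[ch]])$intensity,
      numeric(1))
    r <- If / P
    # channels carrying almost no light give unstable ratios
    r[P < 0.005 * sum(P)] <- 1
    g[ie, ix, id, ] <- pmin(pmax(r, 0.5), 2)
  }
  structure(list(eta = eta, xi = xi, delta = delta, g = g,
                 estimator = estimator), class = "fp_response")
}

# trilinear interpolation of the response factors (xi periodic mod 180)
interp_response <- function(resp, eta, xi, delta) {
  if (is.null(resp)) return(rep(1, 4))
  loc <- function(ax, v, periodic = FALSE) {
    if (periodic) v <- v %% 180
    v <- min(max(v, ax[1]), ax[length(ax)])
    i <- findInterval(v, ax, rightmost.closed = TRUE)
    i <- min(i, length(ax) - 1)
    w <- (v - ax[i]) / (ax[i + 1] - ax[i])
    c(i, w)
  }
  le <- loc(resp$eta, eta); lx <- loc(resp$xi, xi, TRUE); ld <- loc(resp$delta, delta)
  out <- numeric(4)
  for (c4 in 1:4) {
    v <- 0
    for (a in 0:1) for (b in 0:1) for (d in 0:1) {
      w <- (if (a) le[2] else 1 - le[2]) * (if (b) lx[2] else 1 - lx[2]) *
           (if (d) ld[2] else 1 - ld[2])
      v <- v + w * resp$g[le[1] + a, lx[1] + b, ld[1] + d, c4]
    }
    out[c4] <- v
  }
  out
}

#' Affine registration of the four channels from bead images
#'
#' Detects beads in every channel, matches them to the reference channel by
#' nearest neighbour after removing the median coarse offset, and fits an
#' affine transform per non-reference channel by least squares.
#'
#' @param bead_images Named list (`I0, I90, I45, I135`) of channel images
#'   (summed bead stacks).
#' @param reference Reference channel.
#' @param pfa,psf_radius Detection settings for [detect_glrt()].
#' @param pixel_nm Pixel size for the residual report.
#' @return Named list of [affine_transform()] (reference maps to itself).
#' @export
fit_channel_registration <- function(bead_images, reference = "I0",
                                     pfa = 1e-4, psf_radius = 1.1,
                                     pixel_nm = 130) {
  cents <- lapply(CHANNELS, function(ch) {
    det <- detect_glrt(bead_images[[ch]], pfa = pfa,
                       psf_radius_fixed = psf_radius)
    if (nrow(det) == 0) return(det)
    purrr::map_dfr(seq_len(nrow(det)), function(i) {
      tryCatch(fit_psf(bead_images[[ch]], det$x[i], det$y[i], "gauss_sym"),
               error = function(e) NULL)
    })
  })
  names(cents) <- CHANNELS
  nref <- nrow(cents[[reference]])
  if (is.null(nref) || nref < 10) {
    stop("insufficient landmarks: fewer than 10 beads in the reference channel",
         call. = FALSE)
  }
  out <- list()
  for (ch in CHANNELS) {
    if (ch == reference) { out[[ch]] <- affine_transform(); next }
    d <- cents[[ch]]
    if (is.null(d) || nrow(d) < 10) {
      stop("insufficient landmarks: fewer than 10 beads in channel ", ch,
           call. = FALSE)
    }
    P <- cbind(d$x, d$y)
    Q <- cbind(cents[[reference]]$x, cents[[reference]]$y)
    off <- c(stats::median(Q[, 1]) - stats::median(P[, 1]),
             stats::median(Q[, 2]) - stats::median(P[, 2]))
    Pc <- sweep(P, 2, -off)
    D <- outer(Pc[, 1], Q[, 1], "-")^2 + outer(Pc[, 2], Q[, 2], "-")^2
    j <- apply(D, 1, which.min)
    keep <- sqrt(D[cbind(seq_len(nrow(P)), j)]) < 3
    if (sum(keep) < 10) {
      stop("insufficient landmarks: fewer than 10 bead matches for ", ch,
           call. = FALSE)
    }
    X <- P[keep, , drop = FALSE]; Y <- Q[j[keep], , drop = FALSE]
    fitx <- stats::lm(Y[, 1] ~ X[, 1] + X[, 2])
    fity <- stats::lm(Y[, 2] ~ X[, 1] + X[, 2])
    A <- unname(rbind(stats::coef(fitx)[2:3], stats::coef(fity)[2:3]))
    b <- unname(c(stats::coef(fitx)[1], stats::coef(fity)[1]))
    res <- sqrt(mean(stats::residuals(fitx)^2 + stats::residuals(fity)^2))
    tf <- affine_transform(A, b, residual_rms_nm = res * pixel_nm)
    if (res > 1) warning("registration residual above one pixel in ", ch)
    out[[ch]] <- tf
  }
  out
}

#' Refine channel registration from paired single molecules
#'
#' Composes the median residual displacement of each channel's detections
#' (relative to the fused positions of the paired molecules) into the
#' existing transforms, as an offset update.
#'
#' @param pair_residuals Named list (per channel) of two-column matrices or
#'   data frames of residual displacements (pixels) of that channel's
#'   detections in the reference frame.
#' @param transforms Current transform list.
#' @param min_pairs Minimum number of pairs required.
#' @return Updated transform list (attribute `refined` indicates success).
#' @export
refine_pairing_offset <- function(pair_residuals, transforms,
                                  min_pairs = 100) {
  n <- min(vapply(pair_residuals, function(r) nrow(as.matrix(r)), integer(1)))
  if (n < min_pairs) {
    warning("too few pairs (", n, " < ", min_pairs, "): refinement skipped")
    attr(transforms, "refined") <- FALSE
    return(transforms)
  }
  for (ch in names(pair_residuals)) {
    r <- as.matrix(pair_residuals[[ch]])
    shift <- c(stats::median(r[, 1]), stats::median(r[, 2]))
    tf <- transforms[[ch]]
    transforms[[ch]] <- affine_transform(tf$A, tf$b - shift,
                                         tf$residual_rms_nm)
  }
  attr(transforms, "refined") <- TRUE
  transforms
}

#' Write / read registration transforms as JSON
#' @param transforms Named list of [affine_transform()].
#' @param path File path.
#' @export
write_registration <- function(transforms, path) {
  jsonlite::write_json(lapply(transforms, function(tf)
    list(A = tf$A, b = tf$b, residual_rms_nm = tf$residual_rms_nm)),
    path, digits = NA, auto_unbox = TRUE, matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_registration
#' @export
read_registration <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(j, function(x) affine_transform(matrix(unlist(x$A), 2, 2, byrow = TRUE),
                                         unlist(x$b), x$residual_rms_nm))
}

#' Drift correction by redundant cross-correlation of temporal bins
#'
#' Renders a 2D localization histogram per temporal bin, estimates the shift
#' of every bin against the first by phase correlation with parabolic
#' sub-pixel interpolation, smooths the shift trace, interpolates it to every
#' frame and subtracts it from the coordinates.
#'
#' @param table Localization tibble with `frame, x_nm, y_nm`.
#' @param frames_per_bin Frames per temporal bin.
#' @param bin_nm Histogram pixel size (nm).
#' @param min_peak Minimum normalized correlation peak; weaker bins are
#'   interpolated from their neighbours.
#' @return The corrected table, with the per-frame drift trace as attribute
#'   `drift` (tibble `frame, dx_nm, dy_nm`).
#' @export
drift_correct <- function(table, frames_per_bin = 3000, bin_nm = 50,
                          min_peak = 0.05) {
  stopifnot(all(c("frame", "x_nm", "y_nm") %in% names(table)))
  nfr <- max(table$frame)
  n_bins <- floor(nfr / frames_per_bin)
  if (n_bins < 2) {
    stop("drift correction needs the table to span at least 2 temporal bins",
         call. = FALSE)
  }
  brks <- seq(0, n_bins * frames_per_bin, by = frames_per_bin)
  table$.bin <- pmin(findInterval(table$frame - 1, brks, left.open = FALSE),
                     n_bins)
  xr <- range(table$x_nm); yr <- range(table$y_nm)
  nx <- max(16, ceiling(diff(xr) / bin_nm) + 1)
  ny <- max(16, ceiling(diff(yr) / bin_nm) + 1)
  hist2 <- function(d) {
    ix <- pmin(pmax(floor((d$x_nm - xr[1]) / bin_nm) + 1, 1), nx)
    iy <- pmin(pmax(floor((d$y_nm - yr[1]) / bin_nm) + 1, 1), ny)
    matrix(tabulate(ix + (iy - 1L) * nx, nbins = nx * ny), nx, ny)
  }
  ref <- hist2(dplyr::filter(table, .data$.bin == 1))
  Fref <- stats::fft(ref)
  shifts <- matrix(0, n_bins, 2)
  ok <- rep(TRUE, n_bins)
  for (b in 2:n_bins) {
    cur <- hist2(dplyr::filter(table, .data$.bin == b))
    X <- Fref * Conj(stats::fft(cur))
    Xn <- X / pmax(Mod(X), 1e-12)
    cc <- Re(stats::fft(Xn, inverse = TRUE)) / length(Xn)
    pk <- which(cc == max(cc), arr.ind = TRUE)[1, ]
    if (max(cc) < min_peak) { ok[b] <- FALSE; next }
    # parabolic sub-pixel refinement with wrap-around neighbours
    sub <- sapply(1:2, function(ax) {
      i <- pk[ax]; n <- dim(cc)[ax]
      idx <- function(k) ((k - 1) %% n) + 1
      v <- if (ax == 1) c(cc[idx(i - 1), pk[2]], cc[i, pk[2]], cc[idx(i + 1), pk[2]])
           else c(cc[pk[1], idx(i - 1)], cc[pk[1], i], cc[pk[1], idx(i + 1)])
      den <- v[1] - 2 * v[2] + v[3]
      if (abs(den) < 1e-12) 0 else 0.5 * (v[1] - v[3]) / den
    })
    sh <- pk - 1 + sub
    sh <- ifelse(sh > c(nx, ny) / 2, sh - c(nx, ny), sh)
    shifts[b, ] <- -sh * bin_nm      # drift of bin b relative to bin 1
  }
  # interpolate skipped bins, then smooth lightly
  tmid <- (seq_len(n_bins) - 0.5) * frames_per_bin
  for (ax in 1:2) {
    if (any(!ok)) {
      shifts[!ok, ax] <- stats::approx(tmid[ok], shifts[ok, ax],
                                       xout = tmid[!ok], rule = 2)$y
    }
  }
  sm <- function(v) {
    if (n_bins >= 4) stats::lowess(tmid, v, f = max(0.3, 3 / n_bins))$y else v
  }
  sx <- sm(shifts[, 1]); sy <- sm(shifts[, 2])
  fr <- seq_len(nfr)
  dx <- stats::approx(tmid, sx, xout = fr, rule = 2)$y
  dy <- stats::approx(tmid, sy, xout = fr, rule = 2)$y
  out <- table
  out$x_nm <- out$x_nm - dx[out$frame]
  out$y_nm <- out$y_nm - dy[out$frame]
  out$.bin <- NULL
  attr(out, "drift") <- tibble::tibble(frame = fr, dx_nm = dx, dy_nm = dy)
  out
}
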