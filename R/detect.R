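#' GLRT single-molecule detection in one channel frame
#'
#' At every pixel a generalized likelihood ratio test compares the hypothesis
#' of a fixed-radius Gaussian peak plus constant offset against offset-only,
#' under a Gaussian noise model, inside a square search window.  The amplitude
#' is fitted by linear least squares, so the test statistic is
#' `T = N log(SS0 / SS1)`, asymptotically chi-squared with one degree of
#' freedom under the null; the threshold is the `1 - pfa` quantile.  Detected
#' peaks are local maxima of the statistic within the window, reported at
#' integer pixel coordinates.
#'
#' @param frame_image Numeric matrix (one channel frame, photons).
#' @param window Odd search-window width in pixels.
#' @param pfa Probability of false alarm per tested pixel.
#' @param psf_radius_fixed Fixed Gaussian radius (pixels) used by the test.
#' @return A tibble with `x, y` (0-based integer pixels), `statistic`,
#'   `amplitude`, and the `pfa` used.
#' @export
detect_glrt <- function(frame_image, window = 11, pfa = 1e-3,
                        psf_radius_fixed = 1.1) {
  stopifnot(window %% 2 == 1, pfa > 0, pfa < 1)
  if (window > min(dim(frame_image))) {
    stop("search window larger than the frame", call. = FALSE)
  }
  half <- (window - 1L) %/% 2L
  g1 <- seq(-half, half)
  kern <- exp(-outer(g1^2, g1^2, "+") / (2 * psf_radius_fixed^2))
  res <- fp_glrt_map(frame_image, half, kern)
  thr <- stats::qchisq(1 - pfa, df = 1)
  Tm <- res$T
  cand <- which(Tm > thr & res$amplitude > 0, arr.ind = TRUE)
  if (nrow(cand) == 0) {
    return(tibble::tibble(x = integer(), y = integer(), statistic = numeric(),
                          amplitude = numeric(), pfa = numeric()))
  }
  # local-maximum filter within the window
  keep <- vapply(seq_len(nrow(cand)), function(k) {
    i <- cand[k, 1]; j <- cand[k, 2]
    i0 <- max(1, i - half); i1 <- min(nrow(Tm), i + half)
    j0 <- max(1, j - half); j1 <- min(ncol(Tm), j + half)
    Tm[i, j] >= max(Tm[i0:i1, j0:j1])
  }, logical(1))
  cand <- cand[keep, , drop = FALSE]
  tibble::tibble(x = as.integer(cand[, 1] - 1L), y = as.integer(cand[, 2] - 1L),
                 statistic = Tm[cand], amplitude = res$amplitude[cand],
                 pfa = pfa)
}

#' Fit one detected PSF
#'
#' Estimates sub-pixel position, integrated intensity, background and radius
#' around an integer-pixel candidate with one of three estimators:
#' `gauss_sym` (isotropic Gaussian, Gauss-Newton), `gauss_rot` (rotated
#' elliptical Gaussian) or `box` (background-subtracted window sum with
#' centroid position; background from the median of a 2-pixel annulus).
#' Position precision is the Cramer-Rao bound of the Gaussian model under
#' Poisson noise with background.
#'
#' @param frame_image Channel frame (photons).
#' @param x,y Candidate position (0-based integer pixels).
#' @param method `"gauss_sym"`, `"gauss_rot"`, `"gauss_fixed"` (symmetric
#'   Gaussian with the radius held at `sigma_start`) or `"box"`.
#' @param window Odd fitting-window width (pixels).
#' @param sigma_start Starting radius for the Gaussian fits (pixels).
#' @return A one-row tibble: `x, y` (sub-pixel, 0-based pixels), `intensity`
#'   (photons), `bg` (photons/pixel), `radius_px`, `rss`, `precision_px`
#'   (CRLB position precision), `method`, `converged`.
#' @export
fit_psf <- function(frame_image, x, y,
                    method = c("gauss_sym", "gauss_rot", "gauss_fixed", "box"),
                    window = 11, sigma_start = 1.1) {
  method <- match.arg(method)
  half <- (window - 1L) %/% 2L
  i <- x + 1L; j <- y + 1L
  if (i - half < 1 || i + half > nrow(frame_image) ||
      j - half < 1 || j + half > ncol(frame_image)) {
    stop("candidate too close to the frame edge for the fitting window",
         call. = FALSE)
  }
  win <- frame_image[(i - half):(i + half), (j - half):(j + half)]
  if (method == "box") {
    return(box_estimate(frame_image, x, y, half))
  }
  mode <- switch(method, gauss_sym = 0L, gauss_rot = 1L, gauss_fixed = 2L)
  fit <- fp_fit_gauss_mode(win, half, half, sigma_start, mode)
  if (!isTRUE(fit$converged)) {
    out <- box_estimate(frame_image, x, y, half)
    out$converged <- FALSE
    out$method <- paste0(method, "_fallback_box")
    return(out)
  }
  xs <- fit$par[1] - half + x
  ys <- fit$par[2] - half + y
  prec <- gauss_crlb_sigma_pos(fit$intensity, fit$sigma, max(fit$bg, 0))
  tibble::tibble(x = xs, y = ys, intensity = max(fit$intensity, 0),
                 bg = fit$bg, radius_px = fit$sigma, rss = fit$rss,
                 precision_px = prec, method = method,
                 converged = TRUE)
}

# box estimator: annulus-median background, centroid position
box_estimate <- function(frame_image, x, y, half) {
  i <- x + 1L; j <- y + 1L
  win <- frame_image[(i - half):(i + half), (j - half):(j + half)]
  a0i <- max(1, i - half - 2); a1i <- min(nrow(frame_image), i + half + 2)
  a0j <- max(1, j - half - 2); a1j <- min(ncol(frame_image), j + half + 2)
  ann <- frame_image[a0i:a1i, a0j:a1j]
  inner <- matrix(FALSE, nrow(ann), ncol(ann))
  inner[(i - half - a0i + 1):(i + half - a0i + 1),
        (j - half - a0j + 1):(j + half - a0j + 1)] <- TRUE
  bg <- stats::median(ann[!inner])
  sub <- win - bg
  total <- sum(sub)
  pos <- if (total > 0) {
    g <- seq(-half, half)
    w <- pmax(sub, 0)
    c(sum(w * matrix(g, nrow(win), ncol(win))) / sum(w),
      sum(w * matrix(g, nrow(win), ncol(win), byrow = TRUE)) / sum(w))
  } else c(0, 0)
  # radius from background-subtracted second moments (clamped)
  w <- pmax(sub, 0)
  g <- seq(-half, half)
  vx <- sum(w * (matrix(g, nrow(win), ncol(win)) - pos[1])^2) / max(sum(w), 1e-9)
  vy <- sum(w * (matrix(g, nrow(win), ncol(win), byrow = TRUE) - pos[2])^2) /
    max(sum(w), 1e-9)
  sig <- sqrt(pmax((vx + vy) / 2, 0.09))
  prec <- gauss_crlb_sigma_pos(max(total, 1), sig, max(bg, 0))
  tibble::tibble(x = x + pos[1], y = y + pos[2], intensity = max(total, 0),
                 bg = bg, radius_px = sig, rss = NA_real_,
                 precision_px = prec, method = "box", converged = TRUE)
}

# closed-form position CRLB of a pixelated Gaussian under Poisson noise with
# uniform background (per-axis standard deviation, pixels)
gauss_crlb_sigma_pos <- function(N, sigma_px, bg, pixel = 1) {
  if (N <= 0) return(Inf)
  sa2 <- sigma_px^2 + pixel^2 / 12
  tau <- 2 * pi * bg * sa2 / (N * pixel^2)
  sqrt(sa2 / N * (16 / 9 + 4 * tau))
}
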