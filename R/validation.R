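#' Monte-Carlo localization performance over an orientation grid
#'
#' Renders isolated molecules at random sub-pixel positions, adds Poisson
#' noise and background, validates each channel with the GLRT (as the
#' pipeline does; channels where the molecule is not detected do not vote),
#' localizes the validated channels with the requested
#' estimator(s), fuses their positions by inverse-variance weights
#' `I/sigma^2` (the position-information weighting, which reduces to
#' intensity weighting for equal radii and suppresses spurious wide fits on
#' nearly dark cross-polarized channels), and
#' summarizes the 2D position error per grid point and estimator: the pooled
#' per-axis standard deviation (precision) and the magnitude of the mean
#' error (bias), in nm, measured against the rendered ground-truth position.
#'
#' @param bank A [psf_bank()].
#' @param eta,xi,delta Grid axes (degrees).
#' @param photons Photon budget per molecule (open-objective definition).
#' @param bg Background photons per pixel per channel.
#' @param n_rep Repeats per grid point.
#' @param estimators Estimators to evaluate (see [fit_psf()]).
#' @param seed RNG seed.
#' @return A tibble: `eta, xi, delta, estimator, n, precision_nm, bias_nm,
#'   bias_x_nm, bias_y_nm`.
#' @export
mc_localization <- function(bank, eta = c(15, 35, 55, 75),
                            xi = c(0, 60, 120), delta = c(30, 100, 160),
                            photons = 5000, bg = 10, n_rep = 50,
                            estimators = c("gauss_sym", "gauss_rot", "box"),
                            seed = NULL) {
  grid <- tidyr::expand_grid(eta = eta, xi = xi, delta = delta)
  px <- bank$config$pixel_size_obj
  F <- bank$window_px
  cen <- (F - 1) / 2
  with_seed(seed, {
    purrr::pmap_dfr(grid, function(eta, xi, delta) {
      m6 <- moments_from_orientation(eta, xi, delta, all_six = TRUE)
      errs <- replicate(n_rep, {
        pos <- cen + stats::runif(2, -0.5, 0.5)
        img <- psf_from_moments(m6, photons, bank, position = pos,
                                frame_size = F)
        true_pos <- attr(img, "position")
        noisy <- lapply(CHANNELS, function(ch)
          matrix(stats::rpois(F * F, img[[ch]] + bg), F, F))
        names(noisy) <- CHANNELS
        detected <- vapply(CHANNELS, function(ch) {
          d <- detect_glrt(noisy[[ch]], pfa = 1e-3,
                           psf_radius_fixed = bank$sigma_px[[ch]])
          nrow(d) > 0 && min(abs(d$x - cen) + abs(d$y - cen)) <= 3
        }, logical(1))
        if (!any(detected)) detected[] <- TRUE
        sapply(estimators, function(est) {
          fits <- lapply(CHANNELS, function(ch) {
            fit_psf(noisy[[ch]], as.integer(cen), as.integer(cen), est,
                    sigma_start = bank$sigma_px[[ch]])
          })
          w <- pmax(vapply(fits, function(f)
            f$intensity / max(f$radius_px, 0.5)^2, numeric(1)), 1e-9)
          w[!detected] <- 0
          xs <- vapply(fits, function(f) f$x, numeric(1))
          ys <- vapply(fits, function(f) f$y, numeric(1))
          # pairing tolerance: channels disagreeing with the strongest
          # detection by more than 2 px would never have been associated
          a <- which.max(w)
          w[abs(xs - xs[a]) > 2 | abs(ys - ys[a]) > 2] <- 0
          fx <- sum(w * xs) / sum(w)
          fy <- sum(w * ys) / sum(w)
          c(fx - true_pos[1], fy - true_pos[2]) * px
        })
      })
      errs <- array(errs, dim = c(2, length(estimators), n_rep))
      purrr::map_dfr(seq_along(estimators), function(k) {
        dx <- errs[1, k, ]; dy <- errs[2, k, ]
        tibble::tibble(eta = eta, xi = xi, delta = delta,
                       estimator = estimators[k], n = n_rep,
                       precision_nm = stats::sd(c(dx - mean(dx),
                                                  dy - mean(dy))),
                       bias_x_nm = mean(dx), bias_y_nm = mean(dy),
                       bias_nm = sqrt(mean(dx)^2 + mean(dy)^2))
      })
    })
  })
}

#' Monte-Carlo orientation-population misclassification
#'
#' Simulates the validation conditions (uniform hemisphere orientations at a
#' fixed wobble, constant photon budget, uniform background), runs the full
#' pipeline (detection, fixed-radius Gaussian intensity estimation,
#' estimator-matched calibration, known-brightness maximum-likelihood
#' retrieval), matches retrievals to ground truth and reports wrong-bin
#' fractions per polar-angle population.
#'
#' @param bank A [psf_bank()].
#' @param n_frames Frames to simulate (10 molecules per 64-px frame each).
#' @param n_per_frame Molecules per frame.
#' @param delta Wobble full apex angle (degrees).
#' @param photons Photons per molecule.
#' @param bg Background photons/pixel/channel.
#' @param estimator Intensity estimator for the pipeline.
#' @param scheme Binning scheme (see [bin_eta()]).
#' @param seed RNG seed.
#' @return The [misclassification_rates()] tibble; the matched molecule table
#'   is attached as attribute `matched`.
#' @export
mc_misclassification <- function(bank, n_frames = 1000, n_per_frame = 10,
                                 delta = 100, photons = 5000, bg = 10,
                                 estimator = "gauss_fixed", scheme = "fig2",
                                 seed = NULL) {
  seeds <- with_seed(seed, sample.int(2^31 - 1, 2))
  scene <- make_scene_random_orientations(n_per_frame, n_frames,
                                          delta_fixed = delta,
                                          photons = photons, seed = seeds[1])
  stk <- render_stack(scene, noise = noise_model(background = bg),
                      bank = bank, seed = seeds[2])
  tab <- run_pipeline(stk, bank, estimator = estimator, retrieval = "ml",
                      known_photons = photons, filter = FALSE)
  m <- match_ground_truth(tab, stk$truth)
  rates <- misclassification_rates(
    dplyr::select(m, "id", "eta"),
    tibble::tibble(id = m$id, eta = m$eta_true),
    scheme)
  attr(rates, "matched") <- m
  rates
}
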