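# Shared forward-model objects, built once per test run.  The reduced pupil
# grid keeps the suite fast while staying within the quadrature tolerances
# asserted in the optics tests.
fp_test_env <- new.env(parent = emptyenv())

test_bank <- function() {
  if (is.null(fp_test_env$bank)) {
    fp_test_env$bank <- psf_bank(optical_config(pupil_samples = 160),
                                 oversample = 8, window_px = 15)
  }
  fp_test_env$bank
}

test_cal <- function(estimator = "gauss_fixed") {
  key <- paste0("cal_", estimator)
  if (is.null(fp_test_env[[key]])) {
    fp_test_env[[key]] <- calibrate_K_estimator(test_bank(), estimator)
  }
  fp_test_env[[key]]
}

# analytic-azimuth radial-quadrature oracle for the integrated K matrix:
# independent of the 2D pupil-grid implementation (closed-form azimuthal
# integrals, 1D radial quadrature at high resolution)
K_radial_oracle <- function(cfg, nu = 20000) {
  arm_rows <- function(NAmax) {
    u <- seq(1e-7, NAmax, length.out = nu)
    du <- u[2] - u[1]
    a <- fourpolar:::pupil_amplitudes(u, cfg)
    w <- u * du
    Apc <- a$Ap * a$c0
    Ixx <- sum(w * (0.75 * pi * Mod(Apc)^2 + 0.75 * pi * Mod(a$As)^2 +
                      0.5 * pi * Re(Apc * Conj(a$As))))
    Iyy <- sum(w * 0.25 * pi * Mod(Apc - a$As)^2)
    Izz <- sum(w * pi * Mod(a$Ap)^2 * a$s0^2)
    rbind(c(Ixx, Iyy, Izz, 0), c(Iyy, Ixx, Izz, 0))
  }
  lo <- arm_rows(cfg$NA_low)
  hi <- arm_rows(cfg$NA_high)
  M45 <- rbind(c(.5, .5, 0, 1), c(.5, .5, 0, -1), c(0, 0, 1, 0),
               c(-.5, .5, 0, 0))
  K <- 0.5 * rbind(lo, hi[1, ] %*% M45, hi[2, ] %*% M45)
  dimnames(K) <- list(c("I0", "I90", "I45", "I135"),
                      c("xx", "yy", "zz", "xy"))
  K
}

# integrated channel intensities predicted by a bank for one molecule
predict_intensities <- function(bank, eta, xi, delta, photons) {
  m <- moments_from_orientation(eta, xi, delta)
  as.vector(bank$K %*% m) / sum(bank$q * m) * photons
}

# angular difference folded into [-90, 90)
fold90 <- function(a) ((a + 90) %% 180) - 90
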