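#' Optical configuration of the four-channel polarization splitter
#'
#' Bundles every optical parameter of the detection path: refractive indices of
#' the sample medium and the glass/immersion side, the objective and the two
#' diaphragm numerical apertures, emission wavelength, object-plane pixel
#' pitch, emitter height above the coverslip, defocus, and the pupil sampling
#' used by the numerical forward model.
#'
#' The two low-NA channels carry the 0/90 degree analyzers and the two high-NA
#' channels (behind the half-wave plate) the effective 45/135 degree
#' analyzers; the assignment of channels to NA arms can be swapped via
#' `channel_arms`.
#'
#' @param n0 Refractive index of the sample medium (water, 1.33).
#' @param n1 Refractive index of glass/immersion (1.515).
#' @param NA_obj Objective numerical aperture.
#' @param NA_low Aperture of the low-NA arm (diaphragm D1).
#' @param NA_high Aperture of the high-NA arm (diaphragm D2). Must not exceed
#'   `n0`: above the critical angle the channel ratios couple to supercritical
#'   emission and the method's assumptions break down.
#' @param wavelength_em Emission wavelength in nm.
#' @param pixel_size_obj Object-plane pixel pitch in nm.
#' @param z0 Emitter height above the coverslip in nm.
#' @param z1 Objective defocus in nm.
#' @param pupil_samples Pupil grid resolution per axis (>= 64).
#' @param channel_arms Named character vector mapping the four channels to
#'   `"low"`/`"high"` NA arms.
#'
#' @return An object of class `optical_config`.
#' @export
optical_config <- function(n0 = 1.33, n1 = 1.515,
                           NA_obj = 1.45, NA_low = 1.1, NA_high = 1.3,
                           wavelength_em = 609, pixel_size_obj = 130,
                           z0 = 0, z1 = 0, pupil_samples = 256,
                           channel_arms = c(I0 = "low", I90 = "low",
                                            I45 = "high", I135 = "high")) {
  cfg <- list(n0 = n0, n1 = n1, NA_obj = NA_obj, NA_low = NA_low,
              NA_high = NA_high, wavelength_em = wavelength_em,
              pixel_size_obj = pixel_size_obj, z0 = z0, z1 = z1,
              pupil_samples = as.integer(pupil_samples),
              channel_arms = channel_arms)
  class(cfg) <- "optical_config"
  validate_optical_config(cfg)
  cfg
}

validate_optical_config <- function(cfg) {
  if (cfg$NA_high > cfg$n0 + 1e-12) {
    stop("sub-critical-angle condition violated: NA_high (", cfg$NA_high,
         ") must not exceed n0 (", cfg$n0, ")", call. = FALSE)
  }
  if (!(cfg$NA_low < cfg$NA_high && cfg$NA_high <= cfg$NA_obj &&
        cfg$NA_obj < cfg$n1)) {
    stop("aperture ordering must satisfy NA_low < NA_high <= NA_obj < n1",
         call. = FALSE)
  }
  if (cfg$pixel_size_obj <= 0) stop("pixel_size_obj must be positive", call. = FALSE)
  if (cfg$pupil_samples < 64L) stop("pupil_samples must be >= 64", call. = FALSE)
  if (cfg$wavelength_em <= 0) stop("wavelength_em must be positive", call. = FALSE)
  stopifnot(setequal(names(cfg$channel_arms), c("I0", "I90", "I45", "I135")),
            all(cfg$channel_arms %in% c("low", "high")))
  invisible(cfg)
}

#' @export
print.optical_config <- function(x, ...) {
  cat("<optical_config>\n")
  cat(sprintf("  n0 = %.3f, n1 = %.3f | NA obj/high/low = %.2f/%.2f/%.2f\n",
              x$n0, x$n1, x$NA_obj, x$NA_high, x$NA_low))
  cat(sprintf("  lambda_em = %g nm, pixel = %g nm, z0 = %g nm, z1 = %g nm\n",
              x$wavelength_em, x$pixel_size_obj, x$z0, x$z1))
  cat(sprintf("  pupil_samples = %d; arms: %s\n", x$pupil_samples,
              paste(names(x$channel_arms), x$channel_arms, sep = ":",
                    collapse = " ")))
  invisible(x)
}

#' Read or write an optical configuration as YAML
#'
#' @param path File path.
#' @return `read_optical_config` returns an `optical_config`;
#'   `write_optical_config` returns `path` invisibly.
#' @export
read_optical_config <- function(path) {
  y <- yaml::read_yaml(path)
  arms <- unlist(y$channel_arms)
  y$channel_arms <- NULL
  do.call(optical_config, c(y, if (length(arms)) list(channel_arms = arms)))
}

#' @rdname read_optical_config
#' @param cfg An `optical_config`.
#' @export
write_optical_config <- function(cfg, path) {
  y <- unclass(cfg)
  y$channel_arms <- as.list(cfg$channel_arms)
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Hash of an optical configuration (for provenance tracking)
#' @param cfg An `optical_config`.
#' @return A short character hash.
#' @export
config_hash <- function(cfg) {
  s <- paste(utils::capture.output(utils::str(unclass(cfg))), collapse = "")
  # small polynomial rolling hash; stable across platforms
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 131 + ch) %% 2147483647
  sprintf("%08x", h)
}

CHANNELS <- c("I0", "I90", "I45", "I135")
MOMENTS  <- c("xx", "yy", "zz", "xy")
MOMENTS6 <- c("xx", "yy", "zz", "xy", "xz", "yz")
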