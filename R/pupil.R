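#' @useDynLib fourpolar, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom rlang .data
NULL

# Radial pupil amplitudes of a dipole above a planar n0/n1 interface.
#
# The emitter sits at height z0 (nm) in medium n0; emission is collected
# through the glass (n1) by an aplanatic objective.  `u` is the transverse
# pupil coordinate n1*sin(theta1) in NA units.  Returns the p- and s-
# amplitudes per unit dipole component, including Fresnel transmission,
# angular-spectrum continuation below/above the critical angle, aplanatic
# apodization (1/sqrt(cos theta1)) and the height/defocus phases.  The overall
# constant is arbitrary; every user-facing quantity is a ratio or is
# normalized downstream.
pupil_amplitudes <- function(u, cfg) {
  n0 <- cfg$n0; n1 <- cfg$n1
  k <- 2 * pi / cfg$wavelength_em
  c1 <- sqrt(pmax(0, 1 - (u / n1)^2))
  s0 <- u / n0
  c0 <- sqrt(as.complex(1 - s0^2))          # imaginary above the critical angle
  ts <- 2 * n0 * c0 / (n0 * c0 + n1 * c1)
  tp <- 2 * n0 * c0 / (n1 * c0 + n0 * c1)
  phase <- exp(1i * k * (n0 * c0 * cfg$z0 + n1 * c1 * cfg$z1))
  scale <- (n1 / n0)^1.5 * sqrt(c1) / c0 * phase
  list(Ap = tp * scale, As = ts * scale, s0 = s0, c0 = c0, c1 = c1)
}

#' Pupil-plane field of a unit dipole
#'
#' Far-field angular spectrum of a dipole along one Cartesian axis, at height
#' `z0` in the sample medium above the coverslip, collected through the glass
#' by an aplanatic objective, mapped to the back focal plane.  Includes the
#' Fresnel p/s transmission at the interface (analytically continued above the
#' critical angle, which carries the supercritical-angle fluorescence), the
#' aplanatic apodization, and the defocus phase.
#'
#' @param axis One of `"x"`, `"y"`, `"z"`: the dipole axis.
#' @param config An [optical_config()].
#' @param NA_mask Aperture radius of the mask (defaults to `NA_obj`).
#' @return An object of class `pupil_field`: a list with complex matrices
#'   `Ex`, `Ey` over the pupil grid, the grid coordinates `u` (NA units), the
#'   logical `mask`, and the generating parameters.
#' @export
build_pupil_field <- function(axis = c("x", "y", "z"), config = optical_config(),
                              NA_mask = config$NA_obj) {
  axis <- match.arg(axis)
  validate_optical_config(config)
  if (NA_mask > config$NA_obj + 1e-12) stop("NA_mask exceeds NA_obj", call. = FALSE)
  n <- config$pupil_samples
  u1 <- seq(-config$NA_obj, config$NA_obj, length.out = n)
  ux <- matrix(u1, n, n)
  uy <- matrix(u1, n, n, byrow = TRUE)
  ur <- sqrt(ux^2 + uy^2)
  mask <- ur <= NA_mask
  phi <- atan2(uy, ux)
  a <- pupil_amplitudes(pmin(ur, config$NA_obj), config)
  mu <- switch(axis, x = c(1, 0, 0), y = c(0, 1, 0), z = c(0, 0, 1))
  cphi <- cos(phi); sphi <- sin(phi)
  Ep <- a$Ap * (a$c0 * (mu[1] * cphi + mu[2] * sphi) + a$s0 * mu[3])
  Es <- a$As * (-mu[1] * sphi + mu[2] * cphi)
  Ex <- (Ep * cphi - Es * sphi) * mask
  Ey <- (Ep * sphi + Es * cphi) * mask
  Ex[!mask] <- 0; Ey[!mask] <- 0
  structure(list(Ex = Ex, Ey = Ey, u = u1, mask = mask, axis = axis,
                 NA_mask = NA_mask, config = config),
            class = "pupil_field")
}

#' @export
print.pupil_field <- function(x, ...) {
  cat(sprintf("<pupil_field> %s-dipole, NA mask %.2f, %dx%d grid\n",
              x$axis, x$NA_mask, nrow(x$Ex), ncol(x$Ex)))
  invisible(x)
}

# Angular power density of an isotropic (unpolarized) emitter vs pupil radius.
# Returns d(power)/du up to a constant, on the radial grid `u`.
isotropic_radial_power <- function(u, cfg) {
  a <- pupil_amplitudes(u, cfg)
  # azimuth-integrated |E|^2 for x/y (each) and z unit dipoles
  Px <- pi * (Mod(a$Ap * a$c0)^2 + Mod(a$As)^2)
  Pz <- 2 * pi * Mod(a$Ap)^2 * a$s0^2
  (2 * Px + Pz) * u
}

#' Collected-power fraction of an unpolarized emitter under an aperture
#'
#' Fraction of the fluorescence of an isotropic (unpolarized) emitter at
#' height `config$z0` above the coverslip that is collected within `NA_cut`,
#' computed by pupil quadrature of the incoherent three-axis dipole sum.
#' With `normalization = "objective"` (default) the reference is the power
#' collected at the full objective aperture; with `"emitted"` it is the total
#' power radiated into both half-spaces (including the uncollected water-side
#' lobe and all glass-side angles).
#'
#' @param config An [optical_config()].
#' @param NA_cut Aperture radius; must not exceed `NA_obj`.
#' @param normalization `"objective"` or `"emitted"`.
#' @param n_quad Radial quadrature points.
#' @return A fraction in \[0, 1\].
#' @export
collection_fraction <- function(config = optical_config(), NA_cut,
                                normalization = c("objective", "emitted"),
                                n_quad = 20000) {
  normalization <- match.arg(normalization)
  validate_optical_config(config)
  if (NA_cut > config$NA_obj + 1e-12) stop("NA_cut exceeds NA_obj", call. = FALSE)
  if (NA_cut <= 0) return(0)
  integ <- function(hi) {
    u <- seq(1e-7, hi, length.out = n_quad)
    sum(isotropic_radial_power(u, config)) * (u[2] - u[1])
  }
  denom <- if (normalization == "objective") integ(config$NA_obj)
           else total_emitted_power(config, n_quad)
  integ(NA_cut) / denom
}

# Total power radiated by an isotropic emitter near the interface (both
# half-spaces), expressed in the same units as the glass-side pupil integral
# of isotropic_radial_power (i.e. the integral over the full glass half-space
# plus the water-side lobe converted with the n1^2/n0 radiometric factor that
# relates pupil-integral units to physical power).  Validated against the
# total-dissipated-power (plane-wave expansion) integral during development.
total_emitted_power <- function(cfg, n_quad = 20000) {
  # glass half-space, integrated over theta1 to handle the grazing edge
  th1 <- seq(1e-7, pi / 2 - 1e-6, length.out = n_quad)
  uu <- cfg$n1 * sin(th1)
  a <- pupil_amplitudes(uu, cfg)
  Px <- pi * (Mod(a$Ap * a$c0)^2 + Mod(a$As)^2)
  Pz <- 2 * pi * Mod(a$Ap)^2 * a$s0^2
  glass <- sum((2 * Px + Pz) * uu * cfg$n1 * cos(th1)) * (th1[2] - th1[1])

  # water half-space: direct + interface-reflected far field
  k <- 2 * pi / cfg$wavelength_em
  th0 <- seq(1e-7, pi / 2 - 1e-6, length.out = n_quad)
  s0 <- sin(th0); c0 <- cos(th0)
  c1 <- sqrt(as.complex(1 - (cfg$n0 * s0 / cfg$n1)^2))
  rs <- (cfg$n0 * c0 - cfg$n1 * c1) / (cfg$n0 * c0 + cfg$n1 * c1)
  rp <- (cfg$n1 * c0 - cfg$n0 * c1) / (cfg$n1 * c0 + cfg$n0 * c1)
  ph <- exp(2i * k * cfg$n0 * c0 * cfg$z0)
  Px_up <- pi * (Mod(1 + rs * ph)^2 + c0^2 * Mod(1 - rp * ph)^2)
  Pz_up <- 2 * pi * s0^2 * Mod(1 + rp * ph)^2
  water_phys <- cfg$n0 * sum((2 * Px_up + Pz_up) * s0) * (th0[2] - th0[1])

  glass + water_phys * cfg$n1^2 / cfg$n0
}
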