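# analytic derivatives of the accessible moments w.r.t. (eta, xi, delta),
# angles in degrees; returns list(m = 4-vector, J = 4x3 matrix, per degree)
moments_and_jacobian <- function(eta, xi, delta) {
  d2r <- pi / 180
  er <- eta * d2r; xr <- xi * d2r
  cc <- cos(delta / 2 * d2r)
  g <- cc * (1 + cc) / 2
  dg_ddelta <- (1 + 2 * cc) / 2 * (-sin(delta / 2 * d2r) / 2) * d2r
  u <- c(sin(er) * cos(xr), sin(er) * sin(xr), cos(er))
  du_deta <- c(cos(er) * cos(xr), cos(er) * sin(xr), -sin(er)) * d2r
  du_dxi <- c(-sin(er) * sin(xr), sin(er) * cos(xr), 0) * d2r
  mfun <- function(u, g) c(g * u[1]^2 + (1 - g) / 3,
                           g * u[2]^2 + (1 - g) / 3,
                           g * u[3]^2 + (1 - g) / 3,
                           g * u[1] * u[2])
  m <- mfun(u, g)
  dm_du <- function(du) c(2 * g * u[1] * du[1], 2 * g * u[2] * du[2],
                          2 * g * u[3] * du[3],
                          g * (du[1] * u[2] + u[1] * du[2]))
  dm_dg <- c(u[1]^2 - 1 / 3, u[2]^2 - 1 / 3, u[3]^2 - 1 / 3, u[1] * u[2])
  J <- cbind(eta = dm_du(du_deta), xi = dm_du(du_dxi),
             delta = dm_dg * dg_ddelta)
  list(m = m, J = J)
}

#' Jacobian of the four channel intensities w.r.t. (eta, xi, delta)
#'
#' Chain rule through the wobble-cone moment model and the integrated
#' propagation matrix.  With the theory normalization (a `q` vector from a
#' [psf_bank()]), the photon count `N` is defined at the open objective and
#' the intensities are `I = N K m / (q . m)`; without `q` the calibration is
#' assumed to absorb the normalization and `I = N K m`.
#'
#' @param omega `c(eta, xi, delta)` in degrees.
#' @param K 4x4 calibration matrix.
#' @param N Total photons.
#' @param q Optional full-aperture normalization vector (length 4).
#' @return 4x3 matrix of `dI_c/dtheta` (photons per degree), with attribute
#'   `intensities`.
#' @export
intensity_jacobian <- function(omega, K, N, q = NULL) {
  mj <- moments_and_jacobian(omega[1], omega[2], omega[3])
  K <- as.matrix(K)
  if (is.null(q)) {
    J <- N * K %*% mj$J
    I <- as.vector(N * K %*% mj$m)
  } else {
    qm <- sum(q * mj$m)
    dqm <- as.vector(t(q) %*% mj$J)
    Km <- as.vector(K %*% mj$m)
    J <- N * (K %*% mj$J * qm - outer(Km, dqm)) / qm^2
    I <- N * Km / qm
  }
  dimnames(J) <- list(CHANNELS, c("eta", "xi", "delta"))
  attr(J, "intensities") <- stats::setNames(I, CHANNELS)
  J
}

# background photons entering each integrated-intensity variance
crlb_background <- function(bg_per_px, bg_area, sigma_px, window) {
  if (is.numeric(bg_area)) return(rep(bg_per_px * bg_area, 4))
  switch(bg_area,
    effective = bg_per_px * 4 * pi * sigma_px^2,
    window = rep(bg_per_px * window^2, 4),
    stop("unknown bg_area", call. = FALSE))
}

#' Cramer-Rao lower bounds on (eta, xi, delta) from integrated intensities
#'
#' Fisher information of the three angular parameters under independent
#' Poisson noise on the four integrated channel intensities with additive
#' background: `F_ij = sum_c dI_c/dtheta_i dI_c/dtheta_j / (I_c + B_c)`.
#' `B_c` is the background variance carried by the intensity estimate of
#' channel `c`; by default the matched-estimator effective area
#' `4 pi sigma_c^2` pixels of background (`bg_area = "effective"`), with the
#' full estimation-window variant (`"window"`) and a user-supplied pixel area
#' also available.
#'
#' @param omega `c(eta, xi, delta)` in degrees.
#' @param K 4x4 calibration matrix.
#' @param N Total photons (open-objective definition when `q` is given).
#' @param bg_per_px Background photons per pixel per channel.
#' @param q Optional normalization vector (see [intensity_jacobian()]).
#' @param bg_area `"effective"`, `"window"`, or a numeric pixel area.
#' @param sigma_px Per-channel PSF radii (pixels) for the effective area.
#' @param window Estimation window width (pixels) for `"window"`.
#' @return Named vector of standard-deviation bounds (degrees); `Inf` with a
#'   `singular` attribute when a parameter is ill-defined at `omega`.
#' @export
crlb_orientation <- function(omega, K, N, bg_per_px = 0, q = NULL,
                             bg_area = "effective",
                             sigma_px = rep(1.1, 4), window = 11) {
  J <- intensity_jacobian(omega, K, N, q)
  I <- attr(J, "intensities")
  B <- crlb_background(bg_per_px, bg_area, sigma_px, window)
  FIM <- t(J) %*% diag(1 / (I + B)) %*% J
  out <- rep(Inf, 3)
  names(out) <- c("eta", "xi", "delta")
  ok <- tryCatch({
    inv <- solve(FIM)
    d <- diag(inv)
    if (any(d < 0)) stop("negative variance")
    out[] <- sqrt(d)
    TRUE
  }, error = function(e) FALSE)
  attr(out, "singular") <- !ok
  attr(out, "fisher") <- FIM
  out
}

#' CRLB map over a grid of orientations
#'
#' @param eta,xi,delta Grid values (degrees); the full outer grid is used.
#' @param K,N,bg_per_px,q,bg_area,sigma_px,window As [crlb_orientation()].
#' @return A tibble of class `fp_crlb_map` with one row per grid point and
#'   columns `sd_eta, sd_xi, sd_delta` (degrees); settings kept as attributes.
#' @export
crlb_map <- function(eta, xi, delta, K, N, bg_per_px = 0, q = NULL,
                     bg_area = "effective", sigma_px = rep(1.1, 4),
                     window = 11) {
  grid <- tidyr::expand_grid(eta = eta, xi = xi, delta = delta)
  if (nrow(grid) == 0) stop("empty grid", call. = FALSE)
  bounds <- purrr::pmap_dfr(grid, function(eta, xi, delta) {
    b <- crlb_orientation(c(eta, xi, delta), K, N, bg_per_px, q,
                          bg_area, sigma_px, window)
    tibble::tibble(sd_eta = b[["eta"]], sd_xi = b[["xi"]],
                   sd_delta = b[["delta"]], singular = attr(b, "singular"))
  })
  out <- dplyr::bind_cols(grid, bounds)
  attr(out, "settings") <- list(N = N, bg_per_px = bg_per_px,
                                bg_area = bg_area, window = window)
  class(out) <- c("fp_crlb_map", class(out))
  out
}

#' @export
glance.fp_crlb_map <- function(x, ...) {
  ok <- dplyr::filter(x, !.data$singular)
  tibble::tibble(
    n_grid = nrow(x), n_singular = sum(x$singular),
    min_sd_eta = min(ok$sd_eta), median_sd_eta = stats::median(ok$sd_eta),
    min_sd_xi = min(ok$sd_xi), median_sd_xi = stats::median(ok$sd_xi),
    min_sd_delta = min(ok$sd_delta),
    median_sd_delta = stats::median(ok$sd_delta))
}

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics tidy
#' @export
generics::tidy

#' Plot a CRLB map slice
#'
#' Heat map of a chosen bound over (eta, delta) at the first xi of the grid.
#'
#' @param object An `fp_crlb_map`.
#' @param parameter `"eta"`, `"xi"` or `"delta"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fp_crlb_map <- function(object, parameter = "delta", ...) {
  col <- paste0("sd_", parameter)
  xi0 <- object$xi[1]
  dat <- dplyr::filter(object, .data$xi == xi0)
  ggplot2::ggplot(dat, ggplot2::aes(.data$eta, .data$delta,
                                    fill = .data[[col]])) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(limits = c(0, stats::quantile(
      dat[[col]][is.finite(dat[[col]])], 0.98))) +
    ggplot2::labs(x = "eta (deg)", y = "delta (deg)",
                  fill = paste0("CRLB sd(", parameter, ") [deg]"),
                  title = sprintf("xi = %g deg", xi0))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
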