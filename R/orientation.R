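#' Cone order parameter of the wobble model
#'
#' A molecule wobbling uniformly (in solid angle) inside a cone of full apex
#' angle `delta` around its mean direction has lab-frame second moments
#' `m = gamma(delta) u u' + (1 - gamma(delta))/3 I`.  With `c = cos(delta/2)`
#' the axial second moment in the cone frame is `(1 + c + c^2)/3`, hence
#' `gamma = c (1 + c) / 2`: 1 for a fixed dipole, 0 in the isotropic limit.
#'
#' @param delta Wobble full apex angle(s) in degrees, in \[0, 180\].
#' @return Order parameter(s) in \[0, 1\].
#' @export
gamma_delta <- function(delta) {
  stopifnot(all(delta >= 0 & delta <= 180))
  cc <- cos(delta / 2 * pi / 180)
  cc * (1 + cc) / 2
}

# inverse of gamma_delta
delta_from_gamma <- function(gamma) {
  gamma <- pmin(1, pmax(0, gamma))
  cc <- (-1 + sqrt(1 + 8 * gamma)) / 2
  2 * acos(pmin(1, pmax(-1, cc))) * 180 / pi
}

#' Second-order dipole moments of a wobbling molecule
#'
#' Maps mean orientation and wobble to the four instrument-accessible
#' second-order moments (and, with `all_six = TRUE`, the two cross terms
#' needed to render the point-spread function shape).
#'
#' @param eta Polar angle in degrees, 0 (vertical, off-plane) to 90 (in-plane).
#' @param xi In-plane azimuth in degrees, defined modulo 180.
#' @param delta Wobble full apex angle in degrees, in \[0, 180\].
#' @param all_six Return all six moments (xx, yy, zz, xy, xz, yz)?
#' @return For scalar input a named numeric vector; for vector input a tibble
#'   with one row per molecule.
#' @export
moments_from_orientation <- function(eta, xi, delta, all_six = FALSE) {
  stopifnot(all(eta >= 0 & eta <= 90), all(delta >= 0 & delta <= 180))
  er <- eta * pi / 180; xr <- xi * pi / 180
  g <- gamma_delta(delta)
  ux <- sin(er) * cos(xr); uy <- sin(er) * sin(xr); uz <- cos(er)
  m <- cbind(xx = g * ux^2 + (1 - g) / 3,
             yy = g * uy^2 + (1 - g) / 3,
             zz = g * uz^2 + (1 - g) / 3,
             xy = g * ux * uy)
  if (all_six) m <- cbind(m, xz = g * ux * uz, yz = g * uy * uz)
  if (length(eta) == 1L && length(xi) == 1L && length(delta) == 1L) m[1, ] else tibble::as_tibble(m)
}

validate_moments <- function(m, tol = 1e-9) {
  m <- as.numeric(m[1:4])
  if (any(m[1:3] < -tol)) stop("diagonal moments must be non-negative", call. = FALSE)
  if (abs(sum(m[1:3]) - 1) > 1e-6) stop("moments must have unit trace", call. = FALSE)
  if (m[4]^2 > m[1] * m[2] + tol) stop("|m_xy| must not exceed sqrt(m_xx m_yy)", call. = FALSE)
  invisible(m)
}

#' Invert integrated channel intensities to second-order moments
#'
#' Applies the inverse of the integrated calibration matrix to the four
#' integrated intensities, renormalizes to unit trace, and projects the result
#' into the physical moment set (non-negative diagonal, bounded cross term).
#' Raw pre-projection values are kept for diagnostics.
#'
#' @param I Tibble or matrix with columns/entries `I0, I90, I45, I135`
#'   (photons), one row per molecule, or a length-4 vector.
#' @param K A 4x4 calibration matrix (channels x moments), e.g.
#'   `basis_psfs(cfg)$K` or a measured [calibrate_K()] matrix.
#' @return A tibble with columns `xx, yy, zz, xy`, the raw (pre-projection)
#'   moments `raw_xx ... raw_xy`, and a logical `clipped` flag.
#' @export
invert_intensities <- function(I, K) {
  if (is.null(dim(I))) I <- matrix(I, nrow = 1)
  I <- as.matrix(I)
  if (ncol(I) != 4) stop("expected four channel intensities", call. = FALSE)
  if (any(!is.finite(I)) || any(I < 0)) {
    stop("channel intensities must be finite and non-negative", call. = FALSE)
  }
  if (any(rowSums(I) <= 0)) stop("empty signal: total intensity must be positive", call. = FALSE)
  Kinv <- tryCatch(solve(K), error = function(e)
    stop("calibration matrix is singular", call. = FALSE))
  raw <- I %*% t(Kinv)
  colnames(raw) <- MOMENTS
  tr <- rowSums(raw[, 1:3, drop = FALSE])
  bad_tr <- tr <= 0
  tr[bad_tr] <- 1
  mn <- raw / tr
  # project into the physical set
  diag3 <- pmax(mn[, 1:3, drop = FALSE], 0)
  diag3 <- diag3 / rowSums(diag3)
  cap <- sqrt(diag3[, 1] * diag3[, 2])
  xy <- pmin(pmax(mn[, 4], -cap), cap)
  clipped <- bad_tr | (rowSums(abs(diag3 - mn[, 1:3, drop = FALSE]) > 1e-12) > 0) |
    (abs(xy - mn[, 4]) > 1e-12)
  out <- tibble::as_tibble(cbind(diag3, xy = xy))
  names(out) <- MOMENTS
  out$clipped <- clipped
  raw <- tibble::as_tibble(raw)
  names(raw) <- paste0("raw_", MOMENTS)
  dplyr::bind_cols(out, raw)
}

#' Retrieve orientation and wobble from second-order moments
#'
#' Analytic inversion of the wobble-cone moment model:
#' `xi = atan2(2 m_xy, m_xx - m_yy) / 2`, the in-plane amplitude
#' `a = sqrt((m_xx - m_yy)^2 + 4 m_xy^2)` gives the order parameter
#' `gamma = (3 (a + m_zz) - 1) / 2`, then `eta = asin(sqrt(a / gamma))` and
#' `delta` from the inverse of [gamma_delta()].  Records whose moments leave
#' the model manifold (so that an analytic argument falls outside its domain)
#' are re-estimated by bounded least squares against the forward model and
#' flagged `refined`; records with ill-defined azimuth (vertical dipole or
#' isotropic wobble) are flagged `ill_defined`.
#'
#' @param m Tibble/matrix with columns `xx, yy, zz, xy` (one row per
#'   molecule) or a length-4 vector.
#' @param refine Always re-minimize from the analytic start (slower; the
#'   default refines only off-manifold records).
#' @return A tibble with `eta, xi, delta` (degrees) and logical flags
#'   `ill_defined`, `refined`.
#' @export
orientation_from_moments <- function(m, refine = FALSE) {
  if (is.null(dim(m))) m <- matrix(m, nrow = 1, dimnames = list(NULL, MOMENTS))
  m <- as.matrix(as.data.frame(m)[, MOMENTS])
  dxy <- m[, "xx"] - m[, "yy"]
  a_in <- sqrt(dxy^2 + 4 * m[, "xy"]^2)
  xi <- 0.5 * atan2(2 * m[, "xy"], dxy) * 180 / pi
  xi <- xi %% 180
  gam <- (3 * (a_in + m[, "zz"]) - 1) / 2
  arg <- a_in / ifelse(gam > 0, gam, NA_real_)
  ok <- is.finite(arg) & arg <= 1 + 1e-9 & gam <= 1 + 1e-9
  eta <- rep(NA_real_, nrow(m))
  eta[ok] <- asin(sqrt(pmin(1, arg[ok]))) * 180 / pi
  delta <- rep(NA_real_, nrow(m))
  delta[ok] <- delta_from_gamma(gam[ok])
  need_fit <- !ok | refine
  for (i in which(need_fit)) {
    start <- c(eta = if (is.finite(eta[i])) eta[i] else 45,
               xi = xi[i],
               delta = if (is.finite(delta[i])) delta[i] else 90)
    fit <- stats::optim(start, function(p) {
      sum((moments_from_orientation(p[1], p[2], p[3]) - m[i, ])^2)
    }, method = "L-BFGS-B", lower = c(0, -45, 0), upper = c(90, 225, 180))
    eta[i] <- fit$par[1]; xi[i] <- fit$par[2] %% 180; delta[i] <- fit$par[3]
  }
  ill <- (a_in < 1e-9 & abs(m[, "xy"]) < 1e-9) | eta < 1e-6 | delta > 180 - 1e-6
  tibble::tibble(eta = unname(eta), xi = unname(xi), delta = unname(delta),
                 ill_defined = unname(ill), refined = unname(!ok & need_fit))
}

#' Maximum-likelihood-weighted orientation retrieval from intensities
#'
#' Refines the analytic moment inversion by minimizing the weighted squared
#' residual of the four measured intensities against the forward model,
#' `sum_c (I_c - alpha K m(Omega))^2 / (I_c + B_c)`, with the molecule
#' brightness `alpha` profiled out in closed form.  The weights approximate
#' the Poisson variance of integrated intensities with background, so the
#' refined estimate approaches the efficiency of the intensity Cramer-Rao
#' bound, and the fold-induced upward bias of the analytic polar-angle
#' estimate is largely removed.
#'
#' @param I Matrix/tibble of intensities (`I0, I90, I45, I135`), one row per
#'   molecule, or a length-4 vector.
#' @param K 4x4 calibration matrix.
#' @param bg_total Background photons inside each intensity estimate: scalar,
#'   length-4 vector, or matrix (rows = molecules).
#' @param start Optional starting angles (tibble with `eta, xi, delta`);
#'   defaults to the analytic inversion.
#' @return A tibble `eta, xi, delta, alpha, wls_residual` plus the analytic
#'   flags.
#' @export
orientation_wls <- function(I, K, bg_total = 0, start = NULL) {
  if (is.null(dim(I))) I <- matrix(I, nrow = 1, dimnames = list(NULL, CHANNELS))
  I <- as.matrix(as.data.frame(I)[, CHANNELS])
  n <- nrow(I)
  B <- if (is.matrix(bg_total)) bg_total
       else matrix(bg_total, n, 4, byrow = length(bg_total) == 4)
  if (is.null(start)) {
    m <- invert_intensities(I, K)
    start <- orientation_from_moments(m[, MOMENTS])
  }
  Kt <- t(as.matrix(K))
  out <- start
  out$alpha <- NA_real_
  out$wls_residual <- NA_real_
  for (i in seq_len(n)) {
    w <- 1 / pmax(I[i, ] + B[i, ], 1)
    Ii <- I[i, ]
    obj <- function(p) {
      mm <- moments_from_orientation(p[1], p[2] %% 180, min(p[3], 180))
      P <- drop(mm %*% Kt)
      alpha <- sum(w * Ii * P) / sum(w * P * P)
      sum(w * (Ii - alpha * P)^2)
    }
    p0 <- c(start$eta[i], start$xi[i], start$delta[i])
    if (!all(is.finite(p0))) p0 <- c(45, 0, 90)
    fit <- tryCatch(
      stats::optim(p0, obj, method = "L-BFGS-B",
                   lower = c(0, p0[2] - 90, 0),
                   upper = c(90, p0[2] + 90, 180),
                   control = list(maxit = 100)),
      error = function(e) list(par = p0, value = obj(p0)))
    out$eta[i] <- fit$par[1]
    out$xi[i] <- fit$par[2] %% 180
    out$delta[i] <- fit$par[3]
    mm <- moments_from_orientation(fit$par[1], fit$par[2] %% 180, fit$par[3])
    P <- drop(mm %*% Kt)
    out$alpha[i] <- sum(w * Ii * P) / sum(w * P * P)
    out$wls_residual[i] <- fit$value
    out$ill_defined[i] <- out$ill_defined[i] | fit$par[3] > 180 - 1e-6 |
      fit$par[1] < 1e-6
  }
  out
}

#' Known-brightness Poisson maximum-likelihood orientation retrieval
#'
#' When the molecular brightness is known (as in Monte-Carlo validation at a
#' fixed photon budget, or with an absolutely calibrated source), the four
#' integrated intensities over-determine the three angles and carry an extra
#' orientation signal: the overall collection efficiency varies with the
#' off-plane angle.  This estimator maximizes the Poisson likelihood of the
#' four background-inclusive counts against the forward model
#' `P_c = N K m(Omega) / (scale q . m) + B_c`, starting from the analytic
#' inversion plus two fixed alternate starts to escape local optima.  It
#' approaches the known-brightness Cramer-Rao bound, unlike the scale-free
#' inversion, whose four observables are exactly consumed by
#' (eta, xi, delta, brightness).
#'
#' @param I Intensities (background-subtracted), rows = molecules.
#' @param K 4x4 calibration matrix.
#' @param q Full-aperture normalization vector.
#' @param photons Known brightness N (photons at the open objective); scalar
#'   or per-molecule vector.
#' @param bg_total Background photons inside each intensity estimate (scalar,
#'   length-4, or matrix).
#' @param scale Calibration photon scale (1 for the theoretical matrix; a
#'   measured matrix carries its own scale).
#' @param start Optional starting angles; defaults to the analytic inversion.
#' @param response Optional [estimator_response()] surface de-biasing the
#'   forward model for the finite-window intensity estimator.
#' @return A tibble `eta, xi, delta` plus flags and the residual deviance.
#' @export
orientation_ml <- function(I, K, q, photons, bg_total = 0, scale = 1,
                           start = NULL, response = NULL) {
  if (is.null(dim(I))) I <- matrix(I, nrow = 1, dimnames = list(NULL, CHANNELS))
  I <- as.matrix(as.data.frame(I)[, CHANNELS])
  n <- nrow(I)
  photons <- rep_len(photons, n)
  B <- if (is.matrix(bg_total)) bg_total
       else matrix(bg_total, n, 4, byrow = length(bg_total) == 4)
  if (is.null(start)) {
    m <- invert_intensities(I, K)
    start <- orientation_from_moments(m[, MOMENTS])
  }
  Kt <- t(as.matrix(K))
  out <- start
  out$deviance <- NA_real_
  for (i in seq_len(n)) {
    yi <- I[i, ] + B[i, ]
    Ni <- photons[i] / scale
    nll <- function(p) {
      e1 <- min(max(p[1], 0), 90); x1 <- p[2] %% 180
      d1 <- min(max(p[3], 0), 180)
      mm <- moments_from_orientation(e1, x1, d1)
      P <- drop(mm %*% Kt) / sum(q * mm) * Ni
      if (!is.null(response)) P <- P * interp_response(response, e1, x1, d1)
      P <- pmax(P + B[i, ], 1e-9)
      sum(P - yi * log(P))
    }
    p0 <- c(start$eta[i], start$xi[i], start$delta[i])
    if (!all(is.finite(p0))) p0 <- c(45, 0, 90)
    best <- NULL
    alt <- if (p0[1] > 45) c(25, p0[2], 100) else c(65, p0[2], 100)
    for (st in list(p0, alt)) {
      f <- tryCatch(
        stats::optim(st, nll, method = "L-BFGS-B",
                     lower = c(0, p0[2] - 90, 0),
                     upper = c(90, p0[2] + 90, 180),
                     control = list(factr = 1e6, maxit = 200)),
        error = function(e) NULL)
      if (!is.null(f) && (is.null(best) || f$value < best$value)) best <- f
    }
    if (is.null(best)) next
    out$eta[i] <- best$par[1]
    out$xi[i] <- best$par[2] %% 180
    out$delta[i] <- min(max(best$par[3], 0), 180)
    out$deviance[i] <- best$value
    out$ill_defined[i] <- out$ill_defined[i] | out$delta[i] > 180 - 1e-6
    out$refined[i] <- TRUE
  }
  out
}

#' Ratiometric polarization observables
#'
#' The two Stokes-like polarization ratios and the low/high-NA arm ratio:
#' `P0 = (I0 - I90)/(I0 + I90)`, `P45 = (I45 - I135)/(I45 + I135)`,
#' `R_NA = (I0 + I90)/(I45 + I135)`.  `P0` and `P45` encode the in-plane
#' azimuth and the degree of polarization (decreasing with wobble); `R_NA`
#' is sensitive to the off-plane tilt via the NA filtering.
#'
#' @param I Tibble/matrix with columns `I0, I90, I45, I135`, or a length-4
#'   vector.
#' @return A tibble with `P0`, `P45`, `R_NA` and a logical `undefined` flag
#'   for zero denominators.
#' @export
ratiometric_observables <- function(I) {
  if (is.null(dim(I))) I <- matrix(I, nrow = 1, dimnames = list(NULL, CHANNELS))
  I <- as.matrix(as.data.frame(I)[, CHANNELS])
  lo <- I[, "I0"] + I[, "I90"]; hi <- I[, "I45"] + I[, "I135"]
  undef <- lo <= 0 | hi <= 0
  tibble::tibble(
    P0 = unname(ifelse(lo > 0, (I[, "I0"] - I[, "I90"]) / lo, NA_real_)),
    P45 = unname(ifelse(hi > 0, (I[, "I45"] - I[, "I135"]) / hi, NA_real_)),
    R_NA = unname(ifelse(hi > 0, lo / hi, NA_real_)),
    undefined = unname(undef))
}
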