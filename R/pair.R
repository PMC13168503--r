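#' Affine channel transform
#'
#' @param A 2x2 linear part.
#' @param b Length-2 offset (pixels).
#' @param residual_rms_nm Registration residual RMS in nm.
#' @return An `affine_transform` object.
#' @export
affine_transform <- function(A = diag(2), b = c(0, 0), residual_rms_nm = 0) {
  if (abs(det(A)) < 1e-12) stop("affine linear part is singular", call. = FALSE)
  structure(list(A = A, b = b, residual_rms_nm = residual_rms_nm),
            class = "affine_transform")
}

#' Apply an affine transform to positions
#' @param xy A two-column matrix (or length-2 vector) of positions.
#' @param tf An [affine_transform()].
#' @return Transformed positions, same shape.
#' @export
apply_affine <- function(xy, tf) {
  v <- is.null(dim(xy))
  if (v) xy <- matrix(xy, nrow = 1)
  out <- xy %*% t(tf$A) + matrix(tf$b, nrow(xy), 2, byrow = TRUE)
  if (v) drop(out) else out
}

identity_transforms <- function() {
  tf <- affine_transform()
  list(I0 = tf, I90 = tf, I45 = tf, I135 = tf)
}

# mutual nearest neighbours between two position sets within per-pair
# tolerance; returns matrix of index pairs
mutual_nn <- function(P, Q, tol) {
  if (nrow(P) == 0 || nrow(Q) == 0) return(cbind(integer(), integer()))
  D <- outer(P[, 1], Q[, 1], "-")^2 + outer(P[, 2], Q[, 2], "-")^2
  iq <- apply(D, 1, which.min)
  ip <- apply(D, 2, which.min)
  keep <- which(ip[iq] == seq_len(nrow(P)))
  d <- sqrt(D[cbind(keep, iq[keep])])
  ok <- d <= tol[cbind(keep, iq[keep])]
  cbind(keep[ok], iq[keep][ok])
}

#' Pair detections of the four polarized channels
#'
#' Maps every per-channel fit into the reference channel frame via the
#' registration transforms, pairs the orthogonal channels of each arm
#' (0 with 90, 45 with 135) by mutual nearest neighbour, then pairs the two
#' arms.  The pairing tolerance is `k` times the combined CRLB localization
#' precision of the two detections (plus a small registration floor).
#' Molecules lacking a detection in any channel are dropped and counted.
#'
#' @param fits_by_channel Named list (`I0, I90, I45, I135`) of tibbles as
#'   returned by [fit_psf()] (columns `x, y, intensity, bg, radius_px,
#'   precision_px`), positions in pixels of their own channel.
#' @param transforms Named list of [affine_transform()] into the reference
#'   channel (default identity).
#' @param k Tolerance multiple of the combined precision.
#' @param floor_px Tolerance floor in pixels.
#' @return A tibble, one row per fully paired molecule: fused `x, y`
#'   (intensity-weighted, reference frame, pixels), the four intensities,
#'   mean background and radius, and `pairing_distance_px`; attribute
#'   `pairing_counts` reports drop statistics.
#' @export
pair_channels <- function(fits_by_channel, transforms = identity_transforms(),
                          k = 3, floor_px = 0.2) {
  f <- lapply(CHANNELS, function(ch) {
    d <- fits_by_channel[[ch]]
    if (is.null(d) || nrow(d) == 0) {
      return(tibble::tibble(x = numeric(), y = numeric(), intensity = numeric(),
                            bg = numeric(), radius_px = numeric(),
                            precision_px = numeric()))
    }
    xy <- apply_affine(cbind(d$x, d$y), transforms[[ch]])
    d$x <- xy[, 1]; d$y <- xy[, 2]
    d
  })
  names(f) <- CHANNELS
  tolm <- function(a, b) {
    outer(pmin(a$precision_px, 2), pmin(b$precision_px, 2),
          function(p, q) k * sqrt(p^2 + q^2)) + floor_px
  }
  pair_arm <- function(a, b) {
    idx <- mutual_nn(cbind(a$x, a$y), cbind(b$x, b$y), tolm(a, b))
    list(a = a[idx[, 1], , drop = FALSE], b = b[idx[, 2], , drop = FALSE])
  }
  lo <- pair_arm(f$I0, f$I90)
  hi <- pair_arm(f$I45, f$I135)
  counts <- c(n_I0 = nrow(f$I0), n_I90 = nrow(f$I90), n_I45 = nrow(f$I45),
              n_I135 = nrow(f$I135), pairs_low = nrow(lo$a),
              pairs_high = nrow(hi$a))
  wmean <- function(a, b, col) {
    (a[[col]] * pmax(a$intensity, 0) + b[[col]] * pmax(b$intensity, 0)) /
      pmax(a$intensity + b$intensity, 1e-9)
  }
  if (nrow(lo$a) == 0 || nrow(hi$a) == 0) {
    out <- empty_paired()
    attr(out, "pairing_counts") <- c(counts, pairs_full = 0)
    return(out)
  }
  Plo <- cbind(wmean(lo$a, lo$b, "x"), wmean(lo$a, lo$b, "y"))
  Phi <- cbind(wmean(hi$a, hi$b, "x"), wmean(hi$a, hi$b, "y"))
  prec_lo <- sqrt(pmin(lo$a$precision_px, 2)^2 + pmin(lo$b$precision_px, 2)^2) / 2
  prec_hi <- sqrt(pmin(hi$a$precision_px, 2)^2 + pmin(hi$b$precision_px, 2)^2) / 2
  tol <- outer(prec_lo, prec_hi, function(p, q) k * sqrt(p^2 + q^2)) + floor_px
  idx <- mutual_nn(Plo, Phi, tol)
  if (nrow(idx) == 0) {
    out <- empty_paired()
    attr(out, "pairing_counts") <- c(counts, pairs_full = 0)
    return(out)
  }
  il <- idx[, 1]; ih <- idx[, 2]
  Itot <- lo$a$intensity[il] + lo$b$intensity[il] +
    hi$a$intensity[ih] + hi$b$intensity[ih]
  fx <- (Plo[il, 1] * (lo$a$intensity + lo$b$intensity)[il] +
         Phi[ih, 1] * (hi$a$intensity + hi$b$intensity)[ih]) / pmax(Itot, 1e-9)
  fy <- (Plo[il, 2] * (lo$a$intensity + lo$b$intensity)[il] +
         Phi[ih, 2] * (hi$a$intensity + hi$b$intensity)[ih]) / pmax(Itot, 1e-9)
  out <- tibble::tibble(
    x = fx, y = fy,
    I0 = lo$a$intensity[il], I90 = lo$b$intensity[il],
    I45 = hi$a$intensity[ih], I135 = hi$b$intensity[ih],
    bg = (lo$a$bg[il] + lo$b$bg[il] + hi$a$bg[ih] + hi$b$bg[ih]) / 4,
    radius_px = (lo$a$radius_px[il] + lo$b$radius_px[il] +
                 hi$a$radius_px[ih] + hi$b$radius_px[ih]) / 4,
    precision_px = sqrt(prec_lo[il]^2 + prec_hi[ih]^2) / 2,
    pairing_distance_px = sqrt(rowSums((Plo[il, , drop = FALSE] -
                                        Phi[ih, , drop = FALSE])^2)))
  attr(out, "pairing_counts") <- c(counts, pairs_full = nrow(out))
  out
}

empty_paired <- function() {
  tibble::tibble(x = numeric(), y = numeric(), I0 = numeric(), I90 = numeric(),
                 I45 = numeric(), I135 = numeric(), bg = numeric(),
                 radius_px = numeric(), precision_px = numeric(),
                 pairing_distance_px = numeric())
}
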