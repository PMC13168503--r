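#' Quadrant layout of the four channels on the camera
#'
#' @param frame_size Per-channel frame width (pixels).
#' @return A tibble with one row per channel: 0-based quadrant origin
#'   `x0, y0` and `size`.
#' @export
quadrant_layout <- function(frame_size) {
  F <- as.integer(frame_size)
  tibble::tibble(channel = CHANNELS,
                 x0 = c(0L, F, 0L, F),
                 y0 = c(0L, 0L, F, F),
                 size = F)
}

validate_layout <- function(layout, frame_dim) {
  stopifnot(all(c("channel", "x0", "y0", "size") %in% names(layout)))
  if (length(unique(layout$size)) != 1) {
    stop("layout error: quadrant sizes differ", call. = FALSE)
  }
  if (any(layout$x0 + layout$size > frame_dim[1]) ||
      any(layout$y0 + layout$size > frame_dim[2])) {
    stop("layout error: quadrants exceed the camera frame", call. = FALSE)
  }
  # disjointness of the axis-aligned rectangles
  for (i in seq_len(nrow(layout) - 1)) for (j in (i + 1):nrow(layout)) {
    a <- layout[i, ]; b <- layout[j, ]
    if (a$x0 < b$x0 + b$size && b$x0 < a$x0 + a$size &&
        a$y0 < b$y0 + b$size && b$y0 < a$y0 + a$size) {
      stop("layout error: quadrants overlap", call. = FALSE)
    }
  }
  invisible(layout)
}

extract_channels <- function(frame, layout) {
  out <- lapply(seq_len(nrow(layout)), function(i) {
    q <- layout[i, ]
    frame[q$x0 + seq_len(q$size), q$y0 + seq_len(q$size)]
  })
  names(out) <- layout$channel
  out
}

# photon counts are stored in 32-bit TIFF samples normalized by this span
# (~1.5e-5 photon quantization; counts above it would clip)
TIFF_COUNT_SPAN <- 65535

#' Write a four-channel stack as multi-page TIFF
#'
#' One 32-bit page per camera frame, quadrant layout preserved; photon counts
#' are scaled into the normalized sample range and recovered exactly (to
#' ~1.5e-5 photons) by [read_stack()].
#'
#' @param stack An `fp_stack` (from [render_stack()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_stack_tiff <- function(stack, path) {
  if (max(stack$frames) > TIFF_COUNT_SPAN) {
    stop("pixel counts exceed the storable span", call. = FALSE)
  }
  pages <- lapply(seq_len(dim(stack$frames)[3]), function(i)
    stack$frames[, , i] / TIFF_COUNT_SPAN)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}

#' Open a stack file for streamed per-frame reading
#'
#' Returns a lightweight reader that loads one camera frame (TIFF page) at a
#' time and splits it into the four channel quadrants, so arbitrarily long
#' stacks are processed at constant memory.
#'
#' @param path TIFF path.
#' @param layout Quadrant layout ([quadrant_layout()]); inferred from the
#'   page size if missing.
#' @return A list: `n_frames`, `dim`, `layout`, and `get_frame(i)` returning
#'   the named list of channel images.
#' @export
read_stack <- function(path, layout = NULL) {
  info <- tiff::readTIFF(path, all = TRUE, payload = FALSE)
  n <- nrow(info)
  first <- tiff::readTIFF(path, all = 1)[[1]]
  if (is.null(layout)) layout <- quadrant_layout(nrow(first) %/% 2L)
  validate_layout(layout, dim(first)[1:2])
  list(
    n_frames = n,
    dim = dim(first)[1:2],
    layout = layout,
    get_frame = function(i) {
      if (i < 1 || i > n) stop("frame index out of range", call. = FALSE)
      pg <- tryCatch(tiff::readTIFF(path, all = i)[[1]],
                     error = function(e)
                       stop("corrupt page at frame ", i, call. = FALSE))
      extract_channels(pg * TIFF_COUNT_SPAN, layout)
    })
}

#' Retrieve orientations for a table of paired intensities
#'
#' Inversion chain intensities -> second-order moments -> (eta, xi, delta),
#' appended to the table.
#'
#' @param paired Tibble with columns `I0, I90, I45, I135` (and, for the
#'   weighted refinement, `bg` and `radius_px`).
#' @param K 4x4 calibration matrix.
#' @param method `"analytic"` (pure inversion, default), `"wls"`
#'   (inversion followed by the intensity-weighted minimization of
#'   [orientation_wls()]) or `"ml"` (known-brightness Poisson maximum
#'   likelihood, [orientation_ml()]; needs `photons` and `q`).
#' @param photons Known per-molecule brightness for `"ml"`.
#' @param q Full-aperture normalization vector for `"ml"`.
#' @param scale Calibration photon scale for `"ml"`.
#' @param response Optional [estimator_response()] surface for `"ml"`.
#' @return The tibble with `eta, xi, delta` and the quality flags.
#' @export
retrieve_orientations <- function(paired, K, method = c("analytic", "wls", "ml"),
                                  photons = NULL, q = NULL, scale = 1,
                                  response = NULL) {
  method <- match.arg(method)
  if (method == "ml" && (is.null(photons) || is.null(q))) {
    stop("ml retrieval needs the known photon budget and the q vector",
         call. = FALSE)
  }
  if (nrow(paired) == 0) {
    return(dplyr::mutate(paired, eta = numeric(0), xi = numeric(0),
                         delta = numeric(0), ill_defined = logical(0),
                         clipped = logical(0), refined = logical(0)))
  }
  I <- as.matrix(paired[, CHANNELS])
  I[I < 0] <- 0
  keep <- rowSums(I) > 0
  m <- invert_intensities(I[keep, , drop = FALSE], K)
  ang <- orientation_from_moments(m[, MOMENTS])
  if (method != "analytic") {
    bg <- if (!is.null(paired$bg)) pmax(paired$bg[keep], 0) else 0
    area <- if (!is.null(paired$radius_px))
      4 * pi * pmax(paired$radius_px[keep], 0.5)^2 else 4 * pi * 1.2^2
    Bm <- matrix(bg * area, sum(keep), 4)
    ang <- if (method == "wls") {
      orientation_wls(I[keep, , drop = FALSE], K, bg_total = Bm, start = ang)
    } else {
      orientation_ml(I[keep, , drop = FALSE], K, q = q, photons = photons,
                     bg_total = Bm, scale = scale, start = ang,
                     response = response)
    }
  }
  out <- paired[keep, , drop = FALSE]
  dplyr::bind_cols(out, ang["eta"], ang["xi"], ang["delta"],
                   ang["ill_defined"], m["clipped"], ang["refined"])
}

#' Full localization and orientation pipeline
#'
#' Per frame and channel: GLRT detection, PSF fitting with the chosen
#' estimator, channel pairing; then moment inversion and orientation
#' retrieval for every fully paired molecule, optional confidence filtering
#' and optional drift correction.
#'
#' @param stack An `fp_stack` from [render_stack()], or a reader from
#'   [read_stack()].
#' @param bank A [psf_bank()]; required in theory-mode (provides the
#'   theoretical calibration and the fixed detection radius).
#' @param calibration A measured [calibrate_K()] result, an
#'   [calibrate_K_estimator()] result, `"estimator"` (default: compute the
#'   estimator-matched synthetic calibration for the chosen estimator) or
#'   `"theory"` (use the bank's theoretical matrix directly).
#' @param transforms Channel registration (default identity, exact for
#'   simulated stacks).
#' @param estimator `"gauss_sym"`, `"gauss_rot"`, `"gauss_fixed"` or `"box"`.
#' @param pfa GLRT false-alarm probability.
#' @param window Detection/fitting window (pixels).
#' @param filter Apply [filter_confidence()]?
#' @param drift Apply [drift_correct()]?
#' @param frames_per_bin Drift-correction bin size.
#' @param retrieval Orientation retrieval method, see
#'   [retrieve_orientations()]; `"ml"` requires `known_photons`.
#' @param known_photons Known molecular brightness (photons, open-objective
#'   definition) for `"ml"` retrieval, e.g. the simulated photon budget of a
#'   Monte-Carlo validation stack.
#' @param progress Print per-stage counts.
#' @return A localization tibble (one row per retained molecule) with
#'   positions in pixels and nm (reference channel frame), the four channel
#'   intensities, total `photons`, background, PSF radius and the retrieval
#'   flags.  Attribute `log` carries per-stage counts; attribute
#'   `config_hash` the optical-configuration hash.
#' @export
run_pipeline <- function(stack, bank, calibration = "estimator",
                         transforms = identity_transforms(),
                         estimator = c("gauss_sym", "gauss_rot",
                                       "gauss_fixed", "box"),
                         pfa = 1e-3, window = 11,
                         filter = TRUE, drift = FALSE, frames_per_bin = 3000,
                         retrieval = "analytic", known_photons = NULL,
                         progress = FALSE) {
  estimator <- match.arg(estimator)
  if (is.character(calibration)) {
    if (missing(bank) || is.null(bank)) {
      stop("config error: a psf_bank is required when no measured ",
           "calibration is given", call. = FALSE)
    }
    calibration <- switch(calibration,
      estimator = calibrate_K_estimator(bank, estimator, window = window),
      theory = theory_calibration(bank),
      stop("unknown calibration mode: ", calibration, call. = FALSE))
  }
  K <- calibration$K
  px_nm <- bank$config$pixel_size_obj
  radius0 <- mean(bank$sigma_px)
  in_memory <- inherits(stack, "fp_stack")
  nfr <- if (in_memory) dim(stack$frames)[3] else stack$n_frames
  layout <- if (in_memory) stack$layout else stack$layout
  get_frame <- if (in_memory) {
    function(i) extract_channels(stack$frames[, , i], layout)
  } else stack$get_frame
  half <- (window - 1L) %/% 2L
  counts <- c(candidates = 0, fitted = 0, paired = 0)
  rows <- vector("list", nfr)
  for (fr in seq_len(nfr)) {
    chans <- get_frame(fr)
    fits <- lapply(CHANNELS, function(ch) {
      img <- chans[[ch]]
      det <- detect_glrt(img, window = window, pfa = pfa,
                         psf_radius_fixed = radius0)
      if (nrow(det) == 0) return(NULL)
      purrr::map_dfr(seq_len(nrow(det)), function(k) {
        if (det$x[k] < half || det$x[k] > nrow(img) - 1 - half ||
            det$y[k] < half || det$y[k] > ncol(img) - 1 - half) return(NULL)
        fit_psf(img, det$x[k], det$y[k], estimator, window = window,
                sigma_start = radius0)
      })
    })
    names(fits) <- CHANNELS
    counts["candidates"] <- counts["candidates"] +
      sum(vapply(fits, function(f) if (is.null(f)) 0L else nrow(f), integer(1)))
    paired <- pair_channels(fits, transforms)
    counts["paired"] <- counts["paired"] + nrow(paired)
    if (nrow(paired) > 0) {
      paired$frame <- fr
      rows[[fr]] <- paired
    }
    if (progress && fr %% 100 == 0) {
      message("frame ", fr, "/", nfr, ": ", counts["paired"], " paired")
    }
  }
  tab <- dplyr::bind_rows(rows)
  if (nrow(tab) == 0) {
    out <- empty_paired()
    out$frame <- integer(0)
    attr(out, "log") <- counts
    return(out)
  }
  response <- NULL
  if (retrieval == "ml") {
    response <- calibration$response
    if (is.null(response)) {
      response <- estimator_response(bank, calibration, estimator,
                                     window = window)
    }
  }
  tab <- retrieve_orientations(tab, K, method = retrieval,
                               photons = known_photons,
                               q = calibration$q,
                               scale = if (is.null(calibration$scale)) 1
                                       else calibration$scale,
                               response = response)
  tab$photons <- tab$I0 + tab$I90 + tab$I45 + tab$I135
  tab$x_px <- tab$x; tab$y_px <- tab$y
  tab$x_nm <- tab$x * px_nm; tab$y_nm <- tab$y * px_nm
  tab$x <- NULL; tab$y <- NULL
  rej <- NULL
  if (filter) {
    tab <- filter_confidence(tab)
    rej <- attr(tab, "rejections")
  }
  if (drift) {
    tab <- drift_correct(tab, frames_per_bin = frames_per_bin)
  }
  attr(tab, "log") <- list(counts = counts, rejections = rej,
                           estimator = estimator, pfa = pfa)
  attr(tab, "config_hash") <- config_hash(bank$config)
  tab
}

#' Write a localization table as CSV
#' @param table Localization tibble.
#' @param path Output path.
#' @export
write_localizations <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}
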