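#' Confidence filtering of retrieved molecules
#'
#' Keeps records with the polar angle strictly inside (5, 88) degrees, the
#' wobble strictly inside (5, 175) degrees, total detected intensity above
#' 1000 photons, and no ill-defined azimuth flag.  Rejection counts per
#' reason are attached as attribute `rejections`.
#'
#' @param table Localization tibble with `eta, delta` and either `photons`
#'   or the four channel intensities; optional `ill_defined` flag.
#' @param eta_range,delta_range Open acceptance intervals (degrees).
#' @param min_photons Minimum total detected intensity.
#' @return The filtered tibble with attribute `rejections`.
#' @export
filter_confidence <- function(table, eta_range = c(5, 88),
                              delta_range = c(5, 175), min_photons = 1000) {
  tb <- tibble::as_tibble(table)
  if (nrow(tb) == 0) {
    attr(tb, "rejections") <- c(eta_range = 0, delta_range = 0,
                                low_photons = 0, ill_defined = 0)
    return(tb)
  }
  photons <- if ("photons" %in% names(tb)) tb$photons
             else tb$I0 + tb$I90 + tb$I45 + tb$I135
  ill <- if ("ill_defined" %in% names(tb)) tb$ill_defined else FALSE
  r_eta <- !(tb$eta > eta_range[1] & tb$eta < eta_range[2])
  r_delta <- !(tb$delta > delta_range[1] & tb$delta < delta_range[2])
  r_phot <- !(photons > min_photons)
  r_ill <- ill & !r_eta & !r_delta & !r_phot
  keep <- !(r_eta | r_delta | r_phot | r_ill)
  out <- tb[keep, , drop = FALSE]
  attr(out, "rejections") <- c(eta_range = sum(r_eta),
                               delta_range = sum(r_delta & !r_eta),
                               low_photons = sum(r_phot & !r_eta & !r_delta),
                               ill_defined = sum(r_ill))
  out
}

# the two published binning schemes for the polar angle
eta_bin_edges <- function(scheme) {
  switch(scheme,
         fig2 = c(30, 60),
         cell = c(40, 60),
         stop("unknown eta binning scheme: ", scheme, call. = FALSE))
}

#' Bin the polar angle into orientation populations
#'
#' Adds a population label per molecule: off-plane, intermediate or in-plane.
#' Two published edge sets are available: `"fig2"` (30/60 degrees) and
#' `"cell"` (40/60 degrees).  A value exactly at an edge goes to the lower
#' bin.
#'
#' @param table Tibble with an `eta` column (degrees).
#' @param scheme `"fig2"` or `"cell"`.
#' @return The tibble with an added factor column `eta_bin` with levels
#'   `off_plane, intermediate, in_plane`.
#' @export
bin_eta <- function(table, scheme = c("fig2", "cell")) {
  scheme <- match.arg(scheme)
  e <- eta_bin_edges(scheme)
  lab <- c("off_plane", "intermediate", "in_plane")
  dplyr::mutate(tibble::as_tibble(table),
    eta_bin = factor(lab[1 + (.data$eta > e[1]) + (.data$eta > e[2])],
                     levels = lab))
}

#' Wrong-population fractions of the retrieved polar angle
#'
#' For each ground-truth population, the fraction of molecules whose
#' retrieved polar-angle bin differs from their true bin (and, for the
#' complementary per-retrieved-class reading, the fraction of each retrieved
#' population that truly belongs elsewhere).
#'
#' @param retrieved Tibble with `id` and retrieved `eta`.
#' @param truth Tibble with `id` and true `eta`.
#' @param scheme Binning scheme, see [bin_eta()].
#' @return A tibble with one row per class: `class`, `n_truth`,
#'   `wrong_fraction` (per ground-truth class), `wrong_fraction_retrieved`
#'   (per retrieved class).
#' @export
misclassification_rates <- function(retrieved, truth, scheme = "fig2") {
  if (!all(c("id", "eta") %in% names(retrieved)) ||
      !all(c("id", "eta") %in% names(truth))) {
    stop("both tables need columns id and eta", call. = FALSE)
  }
  j <- dplyr::inner_join(
    dplyr::select(bin_eta(retrieved, scheme), "id", ret_bin = "eta_bin"),
    dplyr::select(bin_eta(truth, scheme), "id", true_bin = "eta_bin"),
    by = "id")
  if (nrow(j) == 0) stop("no matching molecule ids between tables", call. = FALSE)
  lev <- levels(j$true_bin)
  per_truth <- j |>
    dplyr::group_by(class = .data$true_bin) |>
    dplyr::summarise(n_truth = dplyr::n(),
                     wrong_fraction = mean(.data$ret_bin != .data$true_bin),
                     .groups = "drop")
  per_ret <- j |>
    dplyr::group_by(class = .data$ret_bin) |>
    dplyr::summarise(wrong_fraction_retrieved =
                       mean(.data$ret_bin != .data$true_bin),
                     .groups = "drop")
  out <- dplyr::left_join(
    tibble::tibble(class = factor(lev, levels = lev)),
    dplyr::left_join(per_truth, per_ret, by = "class"), by = "class")
  out$n_truth[is.na(out$n_truth)] <- 0L
  out
}

#' Match retrieved localizations to ground-truth molecules
#'
#' Nearest-neighbour match per frame between a localization table and a
#' rendered scene's ground truth, within a distance tolerance.  Truth columns
#' are appended with a `_true` suffix.
#'
#' @param table Localization tibble (`frame, x_nm, y_nm`).
#' @param truth Ground-truth tibble from [render_stack()] (`frame, x_nm,
#'   y_nm, id, eta, xi, delta, photons`).
#' @param max_dist_nm Match tolerance.
#' @return The matched rows of `table` with `id` and `*_true` columns, plus
#'   position errors `dx_nm, dy_nm`.
#' @export
match_ground_truth <- function(table, truth, max_dist_nm = 260) {
  purrr::map_dfr(split(table, table$frame), function(d) {
    tr <- truth[truth$frame == d$frame[1], ]
    if (nrow(tr) == 0) return(NULL)
    D <- outer(d$x_nm, tr$x_nm, "-")^2 + outer(d$y_nm, tr$y_nm, "-")^2
    j <- apply(D, 1, which.min)
    dist <- sqrt(D[cbind(seq_len(nrow(d)), j)])
    keep <- dist <= max_dist_nm
    if (!any(keep)) return(NULL)
    out <- d[keep, , drop = FALSE]
    sel <- tr[j[keep], ]
    out$id <- sel$id
    out$eta_true <- sel$eta
    out$xi_true <- sel$xi
    out$delta_true <- sel$delta
    out$photons_true <- sel$photons
    out$dx_nm <- out$x_nm - sel$x_nm
    out$dy_nm <- out$y_nm - sel$y_nm
    out
  })
}

#' Region of interest
#' @param x_nm,y_nm Center coordinates (nm).
#' @param radius_nm Radius (nm).
#' @param label Optional label (e.g. "in"/"out").
#' @return A one-row tibble.
#' @export
roi_spec <- function(x_nm, y_nm, radius_nm, label = "roi") {
  stopifnot(radius_nm > 0)
  tibble::tibble(x_nm = x_nm, y_nm = y_nm, radius_nm = radius_nm,
                 label = label)
}

# distance to ROI center and radial direction per localization, all ROIs
roi_geometry <- function(table, rois) {
  rois <- tibble::as_tibble(rois)
  if (nrow(rois) == 0) stop("rois must be non-empty", call. = FALSE)
  purrr::map_dfr(seq_len(nrow(rois)), function(ri) {
    r <- rois[ri, ]
    d <- sqrt((table$x_nm - r$x_nm)^2 + (table$y_nm - r$y_nm)^2)
    inside <- d <= r$radius_nm & d > 0         # exact center is undefined
    out <- table[inside, , drop = FALSE]
    out$roi <- r$label
    out$d_nm <- d[inside]
    out$radial_deg <- (atan2(table$y_nm[inside] - r$y_nm,
                             table$x_nm[inside] - r$x_nm) * 180 / pi) %% 180
    out
  })
}

# fold an angular difference into [-90, 90) using the 180-degree stick symmetry
fold_180 <- function(a) {
  ((a + 90) %% 180) - 90
}

#' Radiality profile around ROI centers
#'
#' For each localization inside an ROI, the radiality `D_xi` is the angular
#' difference (mod 180, folded into \[-90, 90\]) between its in-plane stick
#' angle `xi` and the direction from the ROI center to the localization.
#' Per distance bin, the fraction of localizations with `|D_xi| < cutoff`
#' is reported (with its binomial standard error and the uniform-null
#' expectation `2 cutoff / 180`).
#'
#' @param table Localization tibble with `x_nm, y_nm, xi`.
#' @param rois ROI tibble ([roi_spec()] rows).
#' @param step_nm Distance bin width (half-open bins `[k step, (k+1) step)`).
#' @param cutoff_deg Radial-alignment cutoff.
#' @return A tibble: `roi, d_bin_nm, n, fraction_radial, se, null_fraction`.
#' @export
radiality_profile <- function(table, rois, step_nm = 10, cutoff_deg = 10) {
  g <- roi_geometry(table, rois)
  if (nrow(g) == 0) {
    warning("no localizations inside any ROI")
    return(tibble::tibble(roi = character(), d_bin_nm = numeric(),
                          n = integer(), fraction_radial = numeric(),
                          se = numeric(), null_fraction = numeric()))
  }
  g$Dxi <- fold_180(g$xi - g$radial_deg)
  g |>
    dplyr::mutate(d_bin_nm = floor(.data$d_nm / step_nm) * step_nm) |>
    dplyr::group_by(.data$roi, .data$d_bin_nm) |>
    dplyr::summarise(n = dplyr::n(),
                     fraction_radial = mean(abs(.data$Dxi) < cutoff_deg),
                     .groups = "drop") |>
    dplyr::mutate(se = sqrt(.data$fraction_radial *
                              (1 - .data$fraction_radial) / .data$n),
                  null_fraction = 2 * cutoff_deg / 180)
}

#' Orientation-population fractions versus distance to ROI centers
#'
#' Per distance bin, the fraction of localizations oriented off-plane
#' (`eta < 40`) and in-plane (`eta > 60`), the cell-imaging binning.
#'
#' @param table Localization tibble with `x_nm, y_nm, eta`.
#' @param rois ROI tibble.
#' @param step_nm Distance bin width.
#' @param scheme Binning scheme for the population edges.
#' @return A tibble: `roi, d_bin_nm, n, frac_off_plane, frac_in_plane,
#'   frac_intermediate`.
#' @export
eta_fraction_profile <- function(table, rois, step_nm = 50, scheme = "cell") {
  g <- roi_geometry(table, rois)
  if (nrow(g) == 0) {
    warning("no localizations inside any ROI")
    return(tibble::tibble(roi = character(), d_bin_nm = numeric(),
                          n = integer(), frac_off_plane = numeric(),
                          frac_intermediate = numeric(),
                          frac_in_plane = numeric()))
  }
  bin_eta(g, scheme) |>
    dplyr::mutate(d_bin_nm = floor(.data$d_nm / step_nm) * step_nm) |>
    dplyr::group_by(.data$roi, .data$d_bin_nm) |>
    dplyr::summarise(n = dplyr::n(),
                     frac_off_plane = mean(.data$eta_bin == "off_plane"),
                     frac_intermediate = mean(.data$eta_bin == "intermediate"),
                     frac_in_plane = mean(.data$eta_bin == "in_plane"),
                     .groups = "drop")
}

#' Focus classes from orientation and PSF radius
#'
#' Labels each molecule `in_plane_in_focus` (eta > 60 and radius < 1.4 px),
#' `off_plane_off_focus` (eta < 40 and radius > 2 px) or `other`, the
#' defocus-based classification used to separate membrane-proximal in-plane
#' filaments from tilted out-of-focus ones.
#'
#' @param table Tibble with `eta` and `radius_px`.
#' @param eta_in,radius_in Thresholds of the in-plane/in-focus class.
#' @param eta_off,radius_off Thresholds of the off-plane/off-focus class.
#' @return The tibble with an added factor column `focus_class`.
#' @export
focus_classes <- function(table, eta_in = 60, radius_in = 1.4,
                          eta_off = 40, radius_off = 2) {
  dplyr::mutate(tibble::as_tibble(table),
    focus_class = factor(dplyr::case_when(
      .data$eta > eta_in & .data$radius_px < radius_in ~ "in_plane_in_focus",
      .data$eta < eta_off & .data$radius_px > radius_off ~ "off_plane_off_focus",
      TRUE ~ "other"),
      levels = c("in_plane_in_focus", "off_plane_off_focus", "other")))
}

#' Polar histogram of the stick angle
#'
#' @param table Tibble with `xi` (degrees, mod 180).
#' @param bin_deg Bin width.
#' @return A tibble `xi_mid, n, density` of class `fp_xi_hist`.
#' @export
xi_polar_histogram <- function(table, bin_deg = 5) {
  br <- seq(0, 180, by = bin_deg)
  h <- hist(table$xi %% 180, breaks = br, plot = FALSE)
  out <- tibble::tibble(xi_mid = h$mids, n = h$counts,
                        density = h$counts / sum(h$counts) / bin_deg)
  class(out) <- c("fp_xi_hist", class(out))
  out
}

#' @export
autoplot.fp_xi_hist <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$xi_mid, .data$n)) +
    ggplot2::geom_col(width = diff(object$xi_mid[1:2]) * 0.9) +
    ggplot2::coord_polar(start = -pi / 2, direction = -1) +
    ggplot2::scale_x_continuous(limits = c(0, 360),
                                breaks = seq(0, 330, 30)) +
    ggplot2::labs(x = "xi (deg, mod 180)", y = "count")
}
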