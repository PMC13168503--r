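#' Rasterized stick map of molecular orientations
#'
#' One line segment ("stick") per molecule, centered at its position and
#' oriented at its in-plane angle `xi`, colored by `xi`, `eta` or `delta`
#' (continuous hue for `xi`/`delta`; binned angular sectors for `eta` when
#' `eta_bins` is given).  The output is a deterministic RGB raster.
#'
#' @param table Localization tibble with `x_nm, y_nm, xi` (and the coloring
#'   column).
#' @param color_by `"xi"`, `"eta"` or `"delta"`.
#' @param stick_length_nm Stick length.
#' @param pixel_nm Render pixel size.
#' @param eta_bins Optional vector of bin edges for binned `eta` coloring.
#' @return An `H x W x 3` array in \[0, 1\] with attribute `extent_nm`.
#' @export
render_stick_map <- function(table, color_by = c("xi", "eta", "delta"),
                             stick_length_nm = 80, pixel_nm = 20,
                             eta_bins = NULL) {
  color_by <- match.arg(color_by)
  if (nrow(table) == 0) stop("table is empty", call. = FALSE)
  xr <- range(table$x_nm) + c(-1, 1) * stick_length_nm
  yr <- range(table$y_nm) + c(-1, 1) * stick_length_nm
  W <- ceiling(diff(xr) / pixel_nm) + 1
  H <- ceiling(diff(yr) / pixel_nm) + 1
  img <- array(0, dim = c(W, H, 3))
  vals <- table[[color_by]]
  cols <- stick_colors(vals, color_by, eta_bins)
  half <- stick_length_nm / 2
  nstep <- max(3, ceiling(stick_length_nm / (pixel_nm / 2)))
  tt <- seq(-half, half, length.out = nstep)
  for (i in seq_len(nrow(table))) {
    a <- table$xi[i] * pi / 180
    xs <- table$x_nm[i] + tt * cos(a)
    ys <- table$y_nm[i] + tt * sin(a)
    ix <- pmin(pmax(round((xs - xr[1]) / pixel_nm) + 1, 1), W)
    iy <- pmin(pmax(round((ys - yr[1]) / pixel_nm) + 1, 1), H)
    for (k in seq_along(ix)) {
      img[ix[k], iy[k], ] <- pmax(img[ix[k], iy[k], ], cols[i, ])
    }
  }
  attr(img, "extent_nm") <- c(x = xr, y = yr)
  attr(img, "pixel_nm") <- pixel_nm
  img
}

# map parameter values to RGB rows
stick_colors <- function(vals, color_by, eta_bins = NULL) {
  if (color_by == "eta" && !is.null(eta_bins)) {
    bin <- findInterval(vals, eta_bins)
    hues <- seq(0, 0.75, length.out = length(eta_bins) + 1)
    return(t(grDevices::col2rgb(grDevices::hsv(hues[bin + 1], 1, 1)) / 255))
  }
  rng <- switch(color_by, xi = c(0, 180), eta = c(0, 90), delta = c(0, 180))
  h <- (vals - rng[1]) / diff(rng)
  if (color_by == "xi") {
    # xi is periodic mod 180: use a cyclic hue
    return(t(grDevices::col2rgb(grDevices::hsv(h %% 1, 1, 1)) / 255))
  }
  t(grDevices::col2rgb(grDevices::hsv(pmin(pmax(h, 0), 1) * 0.75, 1, 1)) / 255)
}

#' Write an RGB raster to PNG
#' @param img Array as from [render_stick_map()].
#' @param path Output path.
#' @export
write_stick_png <- function(img, path) {
  # transpose to the row-major orientation png expects (y down)
  a <- aperm(img, c(2, 1, 3))[dim(img)[2]:1, , , drop = FALSE]
  png::writePNG(a, path)
  invisible(path)
}

#' ggplot stick map
#'
#' Vector-graphics variant of [render_stick_map()] built on `geom_spoke`.
#'
#' @param table Localization tibble.
#' @param color_by Coloring parameter.
#' @param stick_length_nm Stick length.
#' @return A ggplot object.
#' @export
plot_stick_map <- function(table, color_by = "eta", stick_length_nm = 80) {
  ggplot2::ggplot(table,
                  ggplot2::aes(.data$x_nm - stick_length_nm / 2 *
                                 cos(.data$xi * pi / 180),
                               .data$y_nm - stick_length_nm / 2 *
                                 sin(.data$xi * pi / 180),
                               angle = .data$xi * pi / 180,
                               colour = .data[[color_by]])) +
    ggplot2::geom_spoke(radius = stick_length_nm) +
    ggplot2::coord_equal() +
    ggplot2::scale_colour_viridis_c() +
    ggplot2::labs(x = "x (nm)", y = "y (nm)")
}
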