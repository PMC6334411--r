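#' Gaussian rendering of localizations
#'
#' The classic SMLM reconstruction: every localization contributes an
#' isotropic 2D Gaussian centred on its position with standard deviation
#' equal to its localization precision. Kernels are evaluated at pixel
#' centres and multiplied by the pixel area (midpoint rule), and truncated
#' beyond `truncate` standard deviations (< 1e-3 of kernel mass at the
#' default 4).
#'
#' With `amplitude = "unit_integral"` each localization carries total mass
#' 1, so pixel intensity reflects both local density and precision; with
#' `"photon_weighted"` each carries its photon count.
#'
#' @param tab a `loc_table` (may be empty, giving a zero image).
#' @param geometry an `image_geometry`.
#' @param amplitude `"unit_integral"` (default) or `"photon_weighted"`.
#' @param truncate kernel truncation radius in standard deviations.
#' @return A `rendered_image` with `mode = "gaussian"`.
#' @export
render_gaussian <- function(tab, geometry,
                            amplitude = c("unit_integral", "photon_weighted"),
                            truncate = 4) {
  amplitude <- match.arg(amplitude)
  validate_loc_table(tab)
  mass <- if (amplitude == "photon_weighted") {
    if (any(is.na(tab$photons))) stop("photon_weighted rendering requires photons")
    tab$photons
  } else rep(1, nrow(tab))
  px <- .accumulate_kernels(tab$x, tab$y, tab$precision, mass, geometry,
                            truncate)
  rendered_image(px, geometry, "gaussian",
                 channel = if (nrow(tab) > 0L) tab$channel[1L] else 1L)
}

#' Count-normalized 2D kernel density rendering
#'
#' Renders the localization density with a global Gaussian kernel bandwidth
#' `h` and expresses pixel values in localizations per square micrometre.
#' The density integrates to the number of contributing localizations
#' (count normalization), so absolute density thresholds are meaningful --
#' the property that makes binary-KDE cluster segmentation quantitative.
#'
#' @param tab a non-empty `loc_table`.
#' @param geometry an `image_geometry`.
#' @param bandwidth kernel standard deviation in nm, or `"auto"` (default):
#'   the mean localization precision of the table, tying smoothing to the
#'   measurement uncertainty.
#' @param truncate kernel truncation radius in bandwidths.
#' @return A `rendered_image` with `mode = "kde"` and
#'   `density_units = "localizations/um^2"`. The bandwidth used is attached
#'   as attribute `"bandwidth"`.
#' @export
render_kde <- function(tab, geometry, bandwidth = "auto", truncate = 4) {
  validate_loc_table(tab)
  if (nrow(tab) == 0L) stop("render_kde: empty localization table")
  h <- if (identical(bandwidth, "auto")) mean(tab$precision) else as.numeric(bandwidth)
  if (!is.finite(h) || h <= 0) stop("render_kde: bandwidth must be > 0")
  ## mass 1e6 per point: per-nm^2 density scaled to localizations/um^2,
  ## divided by the pixel area the accumulator multiplies in.
  scale <- 1e6 / geometry$pixel_size^2
  px <- .accumulate_kernels(tab$x, tab$y, rep(h, nrow(tab)),
                            rep(scale, nrow(tab)), geometry, truncate)
  out <- rendered_image(px, geometry, "kde",
                        channel = tab$channel[1L],
                        density_units = "localizations/um^2")
  attr(out, "bandwidth") <- h
  out
}

## Shared kernel accumulator. For each point adds
##   mass * pixel_area / (2 pi sigma^2) * exp(-(dx^2+dy^2) / (2 sigma^2))
## over the square window |dx|,|dy| <= truncate*sigma, evaluated at pixel
## centres. Coordinates are reduced to the grid origin before any pixel
## arithmetic so results depend only on (x - x0, y - y0).
.accumulate_kernels <- function(x, y, sigma, mass, geom, truncate) {
  px <- matrix(0, nrow = geom$height, ncol = geom$width)
  if (length(x) == 0L) return(px)
  ps <- geom$pixel_size
  area <- ps^2
  rx <- x - geom$x0
  ry <- y - geom$y0
  for (k in seq_along(x)) {
    s <- sigma[k]
    r <- truncate * s
    i0 <- max(0L, as.integer(floor((rx[k] - r) / ps)))
    i1 <- min(geom$width - 1L, as.integer(floor((rx[k] + r) / ps)))
    j0 <- max(0L, as.integer(floor((ry[k] - r) / ps)))
    j1 <- min(geom$height - 1L, as.integer(floor((ry[k] + r) / ps)))
    if (i0 > i1 || j0 > j1) next
    dx <- (i0:i1 + 0.5) * ps - rx[k]
    dy <- (j0:j1 + 0.5) * ps - ry[k]
    amp <- mass[k] * area / (2 * pi * s^2)
    patch <- amp * outer(exp(-dy^2 / (2 * s^2)), exp(-dx^2 / (2 * s^2)))
    px[(j0:j1) + 1L, (i0:i1) + 1L] <- px[(j0:j1) + 1L, (i0:i1) + 1L] + patch
  }
  px
}

#' Additive RGB composite of co-registered channel renders
#'
#' Each input image is rescaled to `[0, 1]` by its own maximum (or a
#' supplied one), multiplied by its channel colour and summed; the result
#' is clipped to `[0, 1]`.
#'
#' @param images list of `rendered_image` with identical geometries.
#' @param colors per-channel colours (any R colour specification);
#'   defaults to green/red/blue for the classic dual-colour overlay.
#' @param max_values optional per-image normalization maxima; defaults to
#'   each image's own maximum.
#' @return An array `height x width x 3` in `[0, 1]`, with attribute
#'   `"geometry"`.
#' @export
composite_channels <- function(images, colors = c("green", "red", "blue"),
                               max_values = NULL) {
  stopifnot(length(images) >= 1L)
  g <- images[[1L]]$geometry
  for (im in images) {
    gi <- im$geometry
    if (gi$width != g$width || gi$height != g$height ||
        gi$pixel_size != g$pixel_size || gi$x0 != g$x0 || gi$y0 != g$y0)
      stop("composite_channels: image geometries differ")
  }
  if (length(colors) < length(images))
    stop("composite_channels: need one colour per image")
  rgb <- array(0, dim = c(g$height, g$width, 3L))
  for (k in seq_along(images)) {
    m <- if (is.null(max_values)) max(images[[k]]$pixels) else max_values[k]
    norm <- if (m > 0) images[[k]]$pixels / m else images[[k]]$pixels
    cc <- grDevices::col2rgb(colors[k])[, 1L] / 255
    for (ch in 1:3) rgb[, , ch] <- rgb[, , ch] + norm * cc[ch]
  }
  rgb[rgb > 1] <- 1
  attr(rgb, "geometry") <- g
  rgb
}

#' Extended scatter plot of localizations
#'
#' Plots raw coordinates with marker radius proportional to a chosen field
#' (localization precision by default) and colour by channel or by a
#' numeric field -- a quick quality-control view that exposes drift and
#' grouping artefacts. Output is deterministic given the table and options.
#'
#' @param tab a `loc_table` (an empty table yields empty axes).
#' @param path output file; `.png` or `.svg` decide the device.
#' @param size_by field name whose values scale marker radius, or a single
#'   number for constant size.
#' @param color_by field name used for colouring; `"channel"` (default)
#'   gives one colour per channel with a legend.
#' @param cex_scale radius multiplier.
#' @param width,height device size in pixels (png) or inches (svg).
#' @return `path`, invisibly.
#' @export
scatter_export <- function(tab, path, size_by = "precision",
                           color_by = "channel", cex_scale = 1,
                           width = 800, height = 800) {
  validate_loc_table(tab)
  if (is.character(size_by) && !(size_by %in% names(tab)))
    stop("unknown size_by field: ", size_by)
  if (!(color_by %in% names(tab)))
    stop("unknown color_by field: ", color_by)
  if (grepl("\\.svg$", path, ignore.case = TRUE)) {
    grDevices::svg(path, width = width / 100, height = height / 100)
  } else {
    grDevices::png(path, width = width, height = height)
  }
  on.exit(grDevices::dev.off(), add = TRUE)
  if (nrow(tab) == 0L) {
    graphics::plot(NA, NA, xlim = c(0, 1), ylim = c(0, 1),
                   xlab = "x (nm)", ylab = "y (nm)", asp = 1)
    return(invisible(path))
  }
  sizes <- if (is.numeric(size_by)) rep(size_by, nrow(tab)) else tab[[size_by]]
  cex <- cex_scale * sizes / mean(sizes)
  if (color_by == "channel") {
    chans <- sort(unique(tab$channel))
    pal <- grDevices::hcl.colors(max(3L, length(chans)), "Dark 3")[seq_along(chans)]
    cols <- pal[match(tab$channel, chans)]
  } else {
    v <- tab[[color_by]]
    pal <- grDevices::hcl.colors(64, "viridis")
    idx <- 1L + as.integer(63 * (v - min(v)) / max(1e-300, diff(range(v))))
    cols <- pal[idx]
  }
  graphics::plot(tab$x, tab$y, pch = 16, cex = cex, col = cols, asp = 1,
                 xlab = "x (nm)", ylab = "y (nm)")
  if (color_by == "channel" && length(unique(tab$channel)) > 1L) {
    chans <- sort(unique(tab$channel))
    graphics::legend("topright", legend = paste("channel", chans),
                     col = pal[seq_along(chans)], pch = 16)
  }
  invisible(path)
}
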