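#' Image geometry: the physical pixel grid of a rendering
#'
#' Pixel `(i, j)` (0-based, `i` along x, `j` along y) covers the half-open
#' physical square `[x0 + i*pixel_size, x0 + (i+1)*pixel_size) x
#' [y0 + j*pixel_size, y0 + (j+1)*pixel_size)` in nm. Rendered pixel grids
#' are stored as matrices with `height` rows (y, row 1 = lowest y bin) and
#' `width` columns (x).
#'
#' @param x0,y0 physical origin (nm) of the lower-left pixel corner.
#' @param pixel_size nm per pixel, > 0. The 5 nm default oversamples the
#'   10-20 nm lateral resolution typical of dSTORM at least twofold.
#' @param width,height pixel counts, >= 1.
#' @return An object of class `image_geometry`.
#' @export
image_geometry <- function(x0, y0, pixel_size = 5, width, height) {
  stopifnot(is.finite(x0), is.finite(y0), pixel_size > 0,
            width >= 1, height >= 1)
  structure(list(x0 = as.numeric(x0), y0 = as.numeric(y0),
                 pixel_size = as.numeric(pixel_size),
                 width = as.integer(width), height = as.integer(height)),
            class = "image_geometry")
}

#' @export
print.image_geometry <- function(x, ...) {
  cat(sprintf("<image_geometry> %d x %d px, %.3g nm/px, origin (%.4g, %.4g) nm\n",
              x$width, x$height, x$pixel_size, x$x0, x$y0))
  invisible(x)
}

#' Geometry covering a localization table
#'
#' Convenience constructor: a grid that covers all localizations with a
#' physical margin on every side.
#'
#' @param tab a `loc_table` with at least one row.
#' @param pixel_size nm per pixel.
#' @param margin margin (nm) added on each side; for quantitative KDE work
#'   use at least 5 bandwidths so kernel mass is not lost off-field.
#' @return An `image_geometry`.
#' @export
geometry_for <- function(tab, pixel_size = 5, margin = 100) {
  validate_loc_table(tab)
  if (nrow(tab) == 0L) stop("cannot derive a geometry from an empty table")
  x0 <- min(tab$x) - margin
  y0 <- min(tab$y) - margin
  width <- ceiling((max(tab$x) + margin - x0) / pixel_size)
  height <- ceiling((max(tab$y) + margin - y0) / pixel_size)
  image_geometry(x0, y0, pixel_size, max(width, 1L), max(height, 1L))
}

## 0-based pixel indices of localizations; NA when off-grid.
## Half-open binning matches the geometry contract.
pixel_index <- function(geom, x, y) {
  i <- floor((x - geom$x0) / geom$pixel_size)
  j <- floor((y - geom$y0) / geom$pixel_size)
  off <- i < 0 | i >= geom$width | j < 0 | j >= geom$height
  i[off] <- NA_integer_
  j[off] <- NA_integer_
  list(i = as.integer(i), j = as.integer(j))
}

#' Construct a rendered image
#'
#' Usually produced by [render_gaussian()], [render_kde()] or
#' [cluster_kde()]; exposed for completeness.
#'
#' @param pixels numeric matrix, `height` rows (y) by `width` columns (x),
#'   finite and (for intensity modes) non-negative.
#' @param geometry the `image_geometry` of the grid.
#' @param mode one of `"gaussian"`, `"kde"`, `"binary"`, `"labels"`.
#' @param channel integer channel id the image was rendered from.
#' @param density_units unit string; `"localizations/um^2"` for KDE images.
#' @return An object of class `rendered_image`.
#' @export
rendered_image <- function(pixels, geometry, mode, channel = 1L,
                           density_units = NULL) {
  stopifnot(inherits(geometry, "image_geometry"),
            is.matrix(pixels),
            nrow(pixels) == geometry$height,
            ncol(pixels) == geometry$width)
  if (!all(is.finite(pixels))) stop("rendered pixels must be finite")
  structure(list(pixels = pixels, geometry = geometry, mode = mode,
                 channel = as.integer(channel),
                 density_units = density_units),
            class = "rendered_image")
}

#' @export
print.rendered_image <- function(x, ...) {
  cat(sprintf("<rendered_image:%s> %d x %d px @ %.3g nm/px, max %.4g%s\n",
              x$mode, x$geometry$width, x$geometry$height,
              x$geometry$pixel_size, max(x$pixels),
              if (is.null(x$density_units)) "" else paste0(" ", x$density_units)))
  invisible(x)
}

#' @export
plot.rendered_image <- function(x, col = grDevices::hcl.colors(256, "inferno"),
                                ...) {
  g <- x$geometry
  graphics::image(x = g$x0 + (seq_len(g$width) - 0.5) * g$pixel_size,
                  y = g$y0 + (seq_len(g$height) - 0.5) * g$pixel_size,
                  z = t(x$pixels), col = col, asp = 1,
                  xlab = "x (nm)", ylab = "y (nm)", useRaster = TRUE, ...)
  invisible(x)
}
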