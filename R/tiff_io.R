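## Minimal baseline TIFF writer.
##
## Quantitative renders (KDE densities, Gaussian intensities) need 32-bit
## IEEE float samples with values far outside [0, 1]; label images need
## 16-bit unsigned samples. The writer emits a single-strip, uncompressed,
## little-endian baseline TIFF with SampleFormat set accordingly, the
## physical pixel size encoded both in the resolution tags (pixels/cm) and
## in an ImageDescription key-value string. tiff::readTIFF() reads these
## files back exactly.

.tiff_rational <- function(value) {
  den <- 1000L
  c(as.integer(round(value * den)), den)
}

.write_tiff_raw <- function(pixels, path, sample_format, description) {
  h <- nrow(pixels); w <- ncol(pixels)
  bps <- if (sample_format == 3L) 32L else 16L
  bytes_px <- bps / 8L
  desc <- c(charToRaw(description), as.raw(0L))  # NUL-terminated
  if (length(desc) %% 2L == 1L) desc <- c(desc, as.raw(0L))

  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  wr2 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  wr4 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")

  ## header
  writeBin(charToRaw("II"), con)
  wr2(42L)
  data_off <- 8L
  data_len <- h * w * bytes_px
  desc_off <- data_off + data_len
  ifd_off <- desc_off + length(desc) + 16L   # desc + 2 rationals (8 bytes each)
  wr4(ifd_off)

  ## pixel data, row-major, matrix row 1 first (row 1 = smallest y bin)
  v <- as.vector(t(pixels))
  if (sample_format == 3L) {
    writeBin(as.numeric(v), con, size = 4, endian = "little")
  } else {
    iv <- as.integer(round(v))
    if (any(iv < 0L) || any(iv > 65535L))
      stop("16-bit TIFF sample out of range [0, 65535]")
    iv[iv > 32767L] <- iv[iv > 32767L] - 65536L   # two's complement uint16
    writeBin(iv, con, size = 2, endian = "little")
  }

  ## out-of-line values: description, x/y resolution rationals
  writeBin(desc, con)
  res <- .tiff_rational(1e7 / attr(pixels, "pixel_size_nm"))
  xres_off <- desc_off + length(desc)
  yres_off <- xres_off + 8L
  wr4(res); wr4(res)

  ## IFD: tags must be sorted ascending
  tag <- function(id, type, count, value, inline_short = (type == 3L)) {
    wr2(id); wr2(type); wr4(count)
    if (inline_short) { wr2(value); wr2(0L) } else wr4(value)
  }
  n_tags <- 14L
  wr2(n_tags)
  tag(256L, 3L, 1L, w)                 # ImageWidth
  tag(257L, 3L, 1L, h)                 # ImageLength
  tag(258L, 3L, 1L, bps)               # BitsPerSample
  tag(259L, 3L, 1L, 1L)                # Compression = none
  tag(262L, 3L, 1L, 1L)                # Photometric = BlackIsZero
  tag(270L, 2L, length(desc), desc_off, inline_short = FALSE)  # Description
  tag(273L, 4L, 1L, data_off, inline_short = FALSE)            # StripOffsets
  tag(277L, 3L, 1L, 1L)                # SamplesPerPixel
  tag(278L, 3L, 1L, h)                 # RowsPerStrip
  tag(279L, 4L, 1L, data_len, inline_short = FALSE)            # StripByteCounts
  tag(282L, 5L, 1L, xres_off, inline_short = FALSE)            # XResolution
  tag(283L, 5L, 1L, yres_off, inline_short = FALSE)            # YResolution
  tag(296L, 3L, 1L, 3L)                # ResolutionUnit = cm
  tag(339L, 3L, 1L, sample_format)     # SampleFormat
  wr4(0L)                              # next IFD
  invisible(path)
}

#' Write a rendered image as a calibrated TIFF
#'
#' Quantitative modes (`gaussian`, `kde`) are written as 32-bit IEEE float
#' samples; `labels` and `binary` images as 16-bit unsigned integers. The
#' physical pixel size is recorded in the TIFF resolution tags and, with
#' the grid origin and mode, in the ImageDescription string. Files read
#' back with [read_image()] (or `tiff::readTIFF`) reproduce pixel values
#' exactly for float modes.
#'
#' @param image a `rendered_image`, or a `height x width x 3` RGB array as
#'   produced by [composite_channels()] (written as float RGB).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  if (is.array(image) && length(dim(image)) == 3L) {
    g <- attr(image, "geometry")
    ps <- if (is.null(g)) NA_real_ else g$pixel_size
    ## RGB composites go through tiff (display, [0,1] by construction)
    tiff::writeTIFF(image, path, bits.per.sample = 8L, reduce = FALSE)
    return(invisible(path))
  }
  stopifnot(inherits(image, "rendered_image"))
  g <- image$geometry
  px <- image$pixels
  attr(px, "pixel_size_nm") <- g$pixel_size
  desc <- sprintf("pixel_size_nm=%.9g;x0=%.9g;y0=%.9g;mode=%s%s",
                  g$pixel_size, g$x0, g$y0, image$mode,
                  if (is.null(image$density_units)) ""
                  else paste0(";units=", image$density_units))
  fmt <- if (image$mode %in% c("labels", "binary")) 1L else 3L
  .write_tiff_raw(px, path, fmt, desc)
  invisible(path)
}

#' Read back a TIFF written by [write_image()]
#'
#' @param path TIFF file path.
#' @return A `rendered_image`; geometry and mode are reconstructed from
#'   the embedded ImageDescription.
#' @export
read_image <- function(path) {
  img <- suppressWarnings(tiff::readTIFF(path, info = TRUE))
  desc <- attr(img, "description")
  if (is.null(desc)) stop("TIFF lacks the calibration description: ", path)
  kv <- strsplit(strsplit(desc, ";")[[1L]], "=")
  vals <- stats::setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
  ps <- as.numeric(vals[["pixel_size_nm"]])
  mode <- vals[["mode"]]
  px <- unclass(img)
  attributes(px) <- list(dim = dim(img))
  if (mode %in% c("labels", "binary")) {
    ## readTIFF scales integer samples to [0,1] by the sample maximum
    px <- round(px * 65535)
  }
  geom <- image_geometry(as.numeric(vals[["x0"]]), as.numeric(vals[["y0"]]),
                         ps, ncol(px), nrow(px))
  rendered_image(px, geom, mode,
                 density_units = if ("units" %in% names(vals)) vals[["units"]]
                 else NULL)
}
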