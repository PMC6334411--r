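#' Per-cluster quantitative features
#'
#' Computes, for every cluster in a labeling, descriptive statistics and
#' shape features of the member localizations:
#' \describe{
#'   \item{n_localizations}{member count}
#'   \item{centroid_x, centroid_y}{mean position (nm)}
#'   \item{mean_precision}{mean localization precision (nm)}
#'   \item{sd_major, sd_minor}{principal-axis standard deviations from the
#'     eigen-decomposition of the 2x2 coordinate covariance (population
#'     form, divisor n)}
#'   \item{orientation}{major-axis angle versus the x-axis, radians in
#'     `(-pi/2, pi/2]`}
#'   \item{elongation}{`sd_major / sd_minor` (>= 1); `NA` when the minor
#'     axis is degenerate (collinear cluster or n = 1)}
#'   \item{fwhm}{cluster size as full width at half maximum,
#'     `2 sqrt(2 ln 2) * sqrt(sd_major * sd_minor)` (nm): the FWHM of the
#'     Gaussian whose geometric-mean spread matches the cluster}
#'   \item{hull_area}{convex hull area (nm^2), 0 when n < 3 or degenerate}
#'   \item{pixel_area}{mask area (nm^2) from the label image when one is
#'     supplied or embedded in the labeling (KDE segmentations), else `NA`}
#' }
#' All features are invariant under translation; all but `orientation` are
#' invariant under rotation.
#'
#' @param tab the `loc_table` that was clustered.
#' @param labeling a `cluster_labeling` aligned with `tab`, or an integer
#'   label vector.
#' @param label_image optional `rendered_image` of mode `"labels"`; taken
#'   from the labeling's `"label_image"` attribute when present.
#' @return A data frame with one row per cluster id 1..K.
#' @examples
#' tab <- loc_table(x = c(0, 0, 10, 10), y = c(0, 10, 0, 10), precision = 10)
#' cluster_features(tab, rep(1L, 4))  # centroid (5,5), hull 100 nm^2
#' @export
cluster_features <- function(tab, labeling, label_image = NULL) {
  validate_loc_table(tab)
  if (inherits(labeling, "cluster_labeling")) {
    if (is.null(label_image)) label_image <- attr(labeling, "label_image")
    labels <- labeling$labels
  } else labels <- as.integer(labeling)
  if (length(labels) != nrow(tab))
    stop("labeling is not aligned with the table")
  k <- max(0L, labels)
  mask_area <- NULL
  if (!is.null(label_image)) {
    ps2 <- label_image$geometry$pixel_size^2
    mask_area <- vapply(seq_len(k),
                        function(id) sum(label_image$pixels == id) * ps2, 0)
  }
  rows <- lapply(seq_len(k), function(id) {
    m <- labels == id
    xs <- tab$x[m]; ys <- tab$y[m]
    n <- sum(m)
    cx <- mean(xs); cy <- mean(ys)
    dxc <- xs - cx; dyc <- ys - cy
    cov <- matrix(c(mean(dxc^2), mean(dxc * dyc),
                    mean(dxc * dyc), mean(dyc^2)), 2L)
    ev <- eigen(cov, symmetric = TRUE)
    lam <- pmax(ev$values, 0)
    sd_major <- sqrt(lam[1L]); sd_minor <- sqrt(lam[2L])
    v <- ev$vectors[, 1L]
    th <- atan2(v[2L], v[1L])
    if (th <= -pi / 2) th <- th + pi
    if (th > pi / 2) th <- th - pi
    data.frame(
      cluster_id = id,
      n_localizations = n,
      centroid_x = cx, centroid_y = cy,
      mean_precision = mean(tab$precision[m]),
      sd_major = sd_major, sd_minor = sd_minor,
      orientation = if (n > 1L) th else NA_real_,
      elongation = if (sd_minor > 0) sd_major / sd_minor else NA_real_,
      fwhm = 2 * sqrt(2 * log(2)) * sqrt(sd_major * sd_minor),
      hull_area = convex_hull_area(xs, ys),
      pixel_area = if (is.null(mask_area)) NA_real_ else mask_area[id]
    )
  })
  out <- if (k > 0L) do.call(rbind, rows) else
    data.frame(cluster_id = integer(0), n_localizations = integer(0),
               centroid_x = numeric(0), centroid_y = numeric(0),
               mean_precision = numeric(0), sd_major = numeric(0),
               sd_minor = numeric(0), orientation = numeric(0),
               elongation = numeric(0), fwhm = numeric(0),
               hull_area = numeric(0), pixel_area = numeric(0))
  rownames(out) <- NULL
  out
}

#' Convex hull area of a point set
#'
#' Shoelace area of the convex hull; 0 for fewer than 3 points or a
#' degenerate (collinear) set.
#'
#' @param x,y coordinates (nm).
#' @return area in nm^2.
#' @export
convex_hull_area <- function(x, y) {
  if (length(x) < 3L) return(0)
  h <- grDevices::chull(x, y)
  if (length(h) < 3L) return(0)
  .shoelace(cbind(x[h], y[h]))
}
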