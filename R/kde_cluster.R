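#' Binary-KDE cluster segmentation
#'
#' Thresholds the count-normalized KDE render at an absolute density and
#' labels the connected foreground components (8-connectivity). Each
#' localization inherits the label of the pixel containing it (0 when the
#' pixel is background or off-grid). Components with fewer than `min_size`
#' member localizations are relabelled noise, and the surviving clusters
#' are renumbered by descending member count.
#'
#' Because the KDE is count-normalized, `density_threshold` has physical
#' units (localizations per square micrometre) and transfers across fields
#' of view and acquisitions.
#'
#' @param tab a non-empty `loc_table`.
#' @param geometry an `image_geometry`; defaults to a grid covering the
#'   table with a margin of five bandwidths.
#' @param bandwidth KDE bandwidth in nm or `"auto"` (mean precision).
#' @param density_threshold mask threshold in localizations/um^2, > 0.
#' @param min_size minimum member count per cluster.
#' @param pixel_size nm per pixel for the default geometry.
#' @return A `cluster_labeling` (`algorithm = "kde"`) with attributes
#'   `"label_image"` (a `rendered_image`, `mode = "labels"`, pixels
#'   carrying final cluster ids) and `"kde_image"` (the underlying render).
#' @export
cluster_kde <- function(tab, geometry = NULL, bandwidth = "auto",
                        density_threshold, min_size = 5, pixel_size = 5) {
  validate_loc_table(tab)
  if (nrow(tab) == 0L) stop("cluster_kde: empty localization table")
  stopifnot(density_threshold > 0)
  if (is.null(geometry)) {
    h0 <- if (identical(bandwidth, "auto")) mean(tab$precision)
          else as.numeric(bandwidth)
    geometry <- geometry_for(tab, pixel_size = pixel_size, margin = 5 * h0)
  }
  kde <- render_kde(tab, geometry, bandwidth = bandwidth)
  mask <- kde$pixels >= density_threshold
  comp <- .label_mask8(mask)

  idx <- pixel_index(geometry, tab$x, tab$y)
  raw <- integer(nrow(tab))
  on_grid <- !is.na(idx$i)
  raw[on_grid] <- comp[cbind(idx$j[on_grid] + 1L, idx$i[on_grid] + 1L)]

  labels <- .finalize_labels(raw, min_size)

  ## re-express the component image in final cluster ids
  remap <- integer(max(comp, 1L))
  surv <- raw > 0L & labels > 0L
  if (any(surv)) remap[raw[surv]] <- labels[surv]
  limg <- matrix(0L, nrow(comp), ncol(comp))
  limg[comp > 0L] <- remap[comp[comp > 0L]]

  out <- cluster_labeling(labels, "kde",
                          list(bandwidth = attr(kde, "bandwidth"),
                               density_threshold = density_threshold,
                               min_size = min_size,
                               pixel_size = geometry$pixel_size))
  attr(out, "label_image") <- rendered_image(limg, geometry, "labels")
  attr(out, "kde_image") <- kde
  out
}

## 8-connectivity labelling of a logical mask. Foreground pixels become
## nodes; edges join horizontally, vertically and diagonally adjacent
## foreground pixels; components come from the graph.
.label_mask8 <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  out <- matrix(0L, h, w)
  fg <- which(mask)
  if (length(fg) == 0L) return(out)
  node <- integer(h * w)
  node[fg] <- seq_along(fg)
  r <- ((fg - 1L) %% h) + 1L
  cc <- ((fg - 1L) %/% h) + 1L
  edges <- NULL
  for (off in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    r2 <- r + off[1L]; c2 <- cc + off[2L]
    ok <- r2 >= 1L & r2 <= h & c2 >= 1L & c2 <= w
    if (!any(ok)) next
    tgt <- (c2[ok] - 1L) * h + r2[ok]
    hit <- node[tgt] > 0L
    if (any(hit))
      edges <- rbind(edges, cbind(node[fg[ok]][hit], node[tgt][hit]))
  }
  memb <- .components(length(fg), edges)
  out[fg] <- memb
  out
}
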