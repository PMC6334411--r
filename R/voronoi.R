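#' Voronoi tessellation of localizations: tile areas and adjacency
#'
#' Computes, for every localization, the area of its Voronoi tile and the
#' identities of its Delaunay neighbours (generators whose tiles share an
#' edge). Tiles are built by clipping a large bounding rectangle with the
#' perpendicular-bisector half-planes of the other generators, visited in
#' order of increasing distance with early termination once no remaining
#' bisector can cut the tile. Tiles that still touch the bounding
#' rectangle are unbounded and reported with area `Inf`.
#'
#' @param tab a `loc_table` (or anything with `x`, `y` columns) of at
#'   least 3 non-collinear, pairwise-distinct points.
#' @return A list with `area` (numeric, `Inf` for unbounded tiles),
#'   `neighbors` (list of integer vectors) and `unbounded` (logical).
#' @export
voronoi_tiles <- function(tab) {
  x <- tab$x; y <- tab$y
  n <- length(x)
  if (n < 3L) stop("voronoi_tiles: need at least 3 points")
  if (anyDuplicated(cbind(x, y)) > 0L)
    stop("voronoi_tiles: duplicate coordinates are not supported")
  xc <- x - mean(x); yc <- y - mean(y)
  cov <- crossprod(cbind(xc, yc)) / n
  if (min(eigen(cov, symmetric = TRUE, only.values = TRUE)$values) <=
      1e-12 * max(1, sum(diag(cov))))
    stop("voronoi_tiles: degenerate (collinear) point set")

  span <- max(max(x) - min(x), max(y) - min(y), 1)
  tol <- 1e-9 * span

  area <- numeric(n)
  neighbors <- vector("list", n)
  unbounded <- logical(n)
  for (i in seq_len(n)) {
    ## bounded tiles can extend far beyond the data (sliver cells near the
    ## hull): enlarge the clipping box until the tile no longer touches it,
    ## or declare the tile unbounded
    for (mf in c(10, 1e3, 1e6)) {
      M <- mf * span
      box <- rbind(c(min(x) - M, min(y) - M), c(max(x) + M, min(y) - M),
                   c(max(x) + M, max(y) + M), c(min(x) - M, max(y) + M))
      cell <- .clip_cell(i, x, y, box, tol, prune = TRUE)
      if (!cell$unbounded) break
    }
    unbounded[i] <- cell$unbounded
    area[i] <- if (cell$unbounded) Inf else cell$area
    neighbors[[i]] <- cell$neighbors
  }
  ## symmetrize adjacency (numerical edge cases can drop one direction)
  for (i in seq_len(n)) for (j in neighbors[[i]])
    if (!(i %in% neighbors[[j]])) neighbors[[j]] <- sort(c(neighbors[[j]], i))
  list(area = area, neighbors = neighbors, unbounded = unbounded)
}

## Clip the bounding box with bisector half-planes around generator i.
## Polygon edges carry a source id: 0 = bounding box, j = bisector of j.
## With prune = TRUE, candidates are visited nearest-first and clipping
## stops once half the next distance exceeds the farthest cell vertex.
.clip_cell <- function(i, x, y, box, tol, prune = TRUE) {
  verts <- box
  src <- rep(0L, nrow(box))
  d2 <- (x - x[i])^2 + (y - y[i])^2
  cand <- setdiff(order(d2), i)
  if (!prune) cand <- setdiff(seq_along(x), i)
  maxd2 <- max((verts[, 1L] - x[i])^2 + (verts[, 2L] - y[i])^2)
  for (j in cand) {
    if (prune && d2[j] > 4 * maxd2) break
    mx <- (x[i] + x[j]) / 2; my <- (y[i] + y[j]) / 2
    dx <- x[j] - x[i]; dy <- y[j] - y[i]
    f <- (verts[, 1L] - mx) * dx + (verts[, 2L] - my) * dy
    if (all(f <= tol)) next          # bisector does not cut
    nv <- nrow(verts)
    new_v <- matrix(0, 0L, 2L); new_s <- integer(0)
    for (k in seq_len(nv)) {
      k2 <- if (k == nv) 1L else k + 1L
      fin <- f[k] <= tol; fin2 <- f[k2] <= tol
      if (fin) {
        new_v <- rbind(new_v, verts[k, ]); new_s <- c(new_s, src[k])
        if (!fin2) {
          t <- f[k] / (f[k] - f[k2])
          new_v <- rbind(new_v, verts[k, ] + t * (verts[k2, ] - verts[k, ]))
          new_s <- c(new_s, j)
        }
      } else if (fin2) {
        t <- f[k] / (f[k] - f[k2])
        new_v <- rbind(new_v, verts[k, ] + t * (verts[k2, ] - verts[k, ]))
        new_s <- c(new_s, src[k])
      }
    }
    if (nrow(new_v) < 3L) { verts <- new_v; src <- new_s; break }
    verts <- new_v; src <- new_s
    maxd2 <- max((verts[, 1L] - x[i])^2 + (verts[, 2L] - y[i])^2)
  }
  if (nrow(verts) < 3L)
    return(list(area = 0, neighbors = integer(0), unbounded = FALSE))
  ## drop sources of degenerate (zero-length) edges
  nv <- nrow(verts)
  nxt <- c(2:nv, 1L)
  elen <- sqrt((verts[nxt, 1L] - verts[, 1L])^2 +
               (verts[nxt, 2L] - verts[, 2L])^2)
  real <- elen > tol
  list(area = .shoelace(verts),
       neighbors = sort(unique(src[real & src > 0L])),
       unbounded = any(real & src == 0L))
}

.shoelace <- function(v) {
  n <- nrow(v)
  nxt <- c(2:n, 1L)
  abs(sum(v[, 1L] * v[nxt, 2L] - v[nxt, 1L] * v[, 2L])) / 2
}

#' Voronoi tile-area cluster segmentation
#'
#' Selects localizations whose Voronoi tile area is below
#' `threshold_factor` times the median tile area (unbounded border tiles
#' are excluded from the median and never selected), then groups selected
#' localizations into clusters by Delaunay-neighbour connectivity. Groups
#' smaller than `min_size` become noise; surviving clusters are renumbered
#' by descending member count. The default factor of 2 selects points at
#' least twice as locally dense as the field median.
#'
#' @param tab a `loc_table` with >= 3 non-collinear localizations.
#' @param threshold_factor tile-area threshold as a multiple of the median
#'   tile area, > 0 (default 2).
#' @param min_size minimum member count per cluster.
#' @return A `cluster_labeling` (`algorithm = "voronoi"`) with attributes
#'   `"tile_area"` (per-localization area, `Inf` when unbounded) and
#'   `"selected"` (logical selection mask before grouping).
#' @export
cluster_voronoi <- function(tab, threshold_factor = 2, min_size = 5) {
  validate_loc_table(tab)
  stopifnot(threshold_factor > 0)
  vt <- voronoi_tiles(tab)
  bounded <- !vt$unbounded
  if (!any(bounded)) {
    labels <- integer(nrow(tab))
  } else {
    med <- stats::median(vt$area[bounded])
    selected <- bounded & vt$area < threshold_factor * med
    sel_idx <- which(selected)
    edges <- NULL
    for (i in sel_idx) {
      js <- vt$neighbors[[i]]
      js <- js[js > i & selected[js]]
      if (length(js) > 0L) edges <- rbind(edges, cbind(i, js))
    }
    raw <- integer(nrow(tab))
    if (length(sel_idx) > 0L) {
      memb <- .components(nrow(tab), edges)
      raw[sel_idx] <- match(memb[sel_idx], unique(memb[sel_idx]))
    }
    labels <- .finalize_labels(raw, min_size)
  }
  out <- cluster_labeling(labels, "voronoi",
                          list(threshold_factor = threshold_factor,
                               min_size = min_size))
  attr(out, "tile_area") <- vt$area
  attr(out, "selected") <- if (any(bounded))
    bounded & vt$area < threshold_factor * stats::median(vt$area[bounded])
    else rep(FALSE, nrow(tab))
  out
}
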