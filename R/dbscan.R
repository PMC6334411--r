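#' DBSCAN clustering of localizations
#'
#' Classic density-based spatial clustering with noise on the 2D Euclidean
#' coordinates. A localization is a core point iff at least `min_pts`
#' localizations (counting itself) lie within `eps`; clusters are the
#' density-connected sets of core points plus the border points they
#' reach. Non-reachable localizations are labelled 0 (noise).
#'
#' The result is deterministic: cluster seeds are taken in ascending row
#' order, expansion is breadth-first, and a border point within `eps` of
#' core points of several clusters joins the cluster claimed first (the
#' one whose lowest-row-id core point comes first).
#'
#' Defaults (`eps` 50 nm, `min_pts` 5) suit dSTORM data with 10-30 nm
#' localization precision: `eps` is about twice the typical precision.
#'
#' @param tab a `loc_table`.
#' @param eps neighbourhood radius in nm, > 0.
#' @param min_pts minimum neighbourhood size (including the point itself)
#'   for a core point, >= 1.
#' @return A `cluster_labeling` with `algorithm = "dbscan"`.
#' @examples
#' tab <- loc_table(x = c(0, 0, 0), y = c(0, 5, 10), precision = 10)
#' cluster_dbscan(tab, eps = 6, min_pts = 2)$labels  # one cluster of 3
#' @export
cluster_dbscan <- function(tab, eps = 50, min_pts = 5) {
  validate_loc_table(tab)
  stopifnot(eps > 0, min_pts >= 1)
  n <- nrow(tab)
  if (n == 0L)
    return(cluster_labeling(integer(0), "dbscan",
                            list(eps = eps, min_pts = min_pts)))
  nb <- .grid_neighbors(tab$x, tab$y, eps)
  is_core <- lengths(nb) >= min_pts
  labels <- integer(n)
  visited <- logical(n)
  cl <- 0L
  for (seed in seq_len(n)) {
    if (visited[seed] || !is_core[seed]) next
    cl <- cl + 1L
    queue <- seed
    visited[seed] <- TRUE
    labels[seed] <- cl
    head <- 1L
    while (head <= length(queue)) {
      p <- queue[head]; head <- head + 1L
      for (q in nb[[p]]) {
        if (labels[q] == 0L && !visited[q]) labels[q] <- cl
        if (is_core[q] && !visited[q]) {
          visited[q] <- TRUE
          labels[q] <- cl
          queue <- c(queue, q)
        }
      }
    }
  }
  labels <- .finalize_labels(labels, min_size = 1L)
  cluster_labeling(labels, "dbscan", list(eps = eps, min_pts = min_pts))
}

## eps-neighbour lists (each point includes itself) via uniform grid
## binning with cell size eps; candidates come from the 3x3 cell block.
## Neighbour lists are in ascending row order.
.grid_neighbors <- function(x, y, eps) {
  n <- length(x)
  cx <- as.integer(floor(x / eps))
  cy <- as.integer(floor(y / eps))
  cells <- new.env(hash = TRUE, parent = emptyenv())
  splits <- split(seq_len(n), paste(cx, cy))
  for (k in names(splits)) assign(k, splits[[k]], envir = cells)
  eps2 <- eps^2
  nb <- vector("list", n)
  for (i in seq_len(n)) {
    cand <- integer(0)
    for (dx in -1:1) for (dy in -1:1) {
      k <- paste(cx[i] + dx, cy[i] + dy)
      hit <- get0(k, envir = cells, inherits = FALSE)
      if (!is.null(hit)) cand <- c(cand, hit)
    }
    d2 <- (x[cand] - x[i])^2 + (y[cand] - y[i])^2
    nb[[i]] <- sort(cand[d2 <= eps2])
  }
  nb
}
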