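# Independent reference implementations used to cross-check the package.
# They deliberately share no code with the implementations under test.

random_loc_table <- function(n, field = 1000, pmin = 5, pmax = 30) {
  loc_table(runif(n, 0, field), runif(n, 0, field), runif(n, pmin, pmax))
}

# Brute-force DBSCAN on the full distance matrix. Core clusters are the
# fixpoint of min-id label propagation over the core-core eps graph;
# border points join the cluster whose minimal core row id is smallest
# (the cluster that would claim them first under seed-ordered expansion).
brute_dbscan <- function(x, y, eps, min_pts) {
  n <- length(x)
  D <- as.matrix(stats::dist(cbind(x, y)))
  nbr <- D <= eps
  is_core <- rowSums(nbr) >= min_pts   # diagonal counts the point itself
  lab <- integer(n)
  cores <- which(is_core)
  if (length(cores) > 0L) {
    cl <- seq_len(n)
    cl[!is_core] <- NA_integer_
    repeat {
      changed <- FALSE
      for (i in cores) {
        m <- min(cl[is_core & nbr[i, ]], cl[i])
        if (m < cl[i]) { cl[i] <- m; changed <- TRUE }
      }
      if (!changed) break
    }
    for (i in seq_len(n)) {
      if (is_core[i]) { lab[i] <- cl[i]; next }
      cand <- cl[is_core & nbr[i, ]]
      if (length(cand) > 0L) lab[i] <- min(cand)
    }
    ids <- sort(unique(lab[lab > 0L]))
    lab[lab > 0L] <- match(lab[lab > 0L], ids)
  }
  lab
}

# canonical form of a labeling: clusters renumbered by first occurrence
canon_labels <- function(lab) {
  out <- integer(length(lab))
  pos <- lab > 0L
  out[pos] <- match(lab[pos], unique(lab[pos]))
  out
}

same_partition <- function(a, b) identical(canon_labels(a), canon_labels(b))

# Queue-based 8-connectivity flood fill of a logical mask.
flood_fill_label <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  k <- 0L
  offs <- rbind(c(-1,-1), c(-1,0), c(-1,1), c(0,-1),
                c(0,1), c(1,-1), c(1,0), c(1,1))
  for (r0 in seq_len(h)) for (c0 in seq_len(w)) {
    if (!mask[r0, c0] || lab[r0, c0] > 0L) next
    k <- k + 1L
    queue <- matrix(c(r0, c0), 1L)
    lab[r0, c0] <- k
    while (nrow(queue) > 0L) {
      cur <- queue[1L, ]; queue <- queue[-1L, , drop = FALSE]
      for (o in seq_len(8L)) {
        r <- cur[1L] + offs[o, 1L]; cc <- cur[2L] + offs[o, 2L]
        if (r >= 1L && r <= h && cc >= 1L && cc <= w &&
            mask[r, cc] && lab[r, cc] == 0L) {
          lab[r, cc] <- k
          queue <- rbind(queue, c(r, cc))
        }
      }
    }
  }
  lab
}

# Brute-force Voronoi tile area for one generator: clip a large box
# against the bisectors of every other generator, no sorting or pruning.
brute_tile <- function(i, x, y, margin_factor = 25) {
  span <- max(max(x) - min(x), max(y) - min(y), 1)
  M <- margin_factor * span
  px <- c(min(x) - M, max(x) + M, max(x) + M, min(x) - M)
  py <- c(min(y) - M, min(y) - M, max(y) + M, max(y) + M)
  box_edge <- rep(TRUE, 4L)
  for (j in seq_along(x)) {
    if (j == i) next
    mx <- (x[i] + x[j]) / 2; my <- (y[i] + y[j]) / 2
    nx <- x[j] - x[i]; ny <- y[j] - y[i]
    f <- (px - mx) * nx + (py - my) * ny
    keep_x <- numeric(0); keep_y <- numeric(0); keep_b <- logical(0)
    nv <- length(px)
    for (k in seq_len(nv)) {
      k2 <- if (k == nv) 1L else k + 1L
      if (f[k] <= 0) {
        keep_x <- c(keep_x, px[k]); keep_y <- c(keep_y, py[k])
        keep_b <- c(keep_b, box_edge[k])
        if (f[k2] > 0) {
          t <- f[k] / (f[k] - f[k2])
          keep_x <- c(keep_x, px[k] + t * (px[k2] - px[k]))
          keep_y <- c(keep_y, py[k] + t * (py[k2] - py[k]))
          keep_b <- c(keep_b, FALSE)
        }
      } else if (f[k2] <= 0) {
        t <- f[k] / (f[k] - f[k2])
        keep_x <- c(keep_x, px[k] + t * (px[k2] - px[k]))
        keep_y <- c(keep_y, py[k] + t * (py[k2] - py[k]))
        keep_b <- c(keep_b, box_edge[k])
      }
    }
    px <- keep_x; py <- keep_y; box_edge <- keep_b
    if (length(px) < 3L) break
  }
  if (length(px) < 3L) return(list(area = 0, unbounded = FALSE))
  nv <- length(px)
  nxt <- c(2:nv, 1L)
  elen <- sqrt((px[nxt] - px)^2 + (py[nxt] - py)^2)
  area <- abs(sum(px * py[nxt] - px[nxt] * py)) / 2
  list(area = area, unbounded = any(box_edge & elen > 1e-9 * span))
}

# selection mask of the Voronoi tile-area rule, computed by brute force;
# tiles still touching the box are re-clipped with a larger one before
# being declared unbounded
brute_voronoi_selection <- function(x, y, factor = 2) {
  cells <- lapply(seq_along(x), function(i) {
    for (mf in c(25, 2.5e3, 2.5e5)) {
      cell <- brute_tile(i, x, y, margin_factor = mf)
      if (!cell$unbounded) break
    }
    cell
  })
  area <- vapply(cells, `[[`, 0, "area")
  unb <- vapply(cells, `[[`, TRUE, "unbounded")
  med <- stats::median(area[!unb])
  !unb & area < factor * med
}
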