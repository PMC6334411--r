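#' Rigid transforms of localization tables
#'
#' A rigid transform is applied as: translate by `(dx, dy)`, rotate by
#' `theta` about the origin, then (if `flip_x`) reflect about the y-axis
#' (negate x). All pairwise distances are preserved.
#'
#' @param dx,dy translation in nm.
#' @param theta rotation in radians, counter-clockwise.
#' @param flip_x logical; reflect about the y-axis after rotation.
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(dx = 0, dy = 0, theta = 0, flip_x = FALSE) {
  stopifnot(is.finite(dx), is.finite(dy), is.finite(theta))
  structure(list(dx = as.numeric(dx), dy = as.numeric(dy),
                 theta = as.numeric(theta), flip_x = isTRUE(flip_x)),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform> d = (%.3f, %.3f) nm, theta = %.4f rad%s\n",
              x$dx, x$dy, x$theta, if (x$flip_x) ", x-flip" else ""))
  invisible(x)
}

#' Apply a rigid transform to a localization table
#'
#' Order of operations: translate, rotate about the origin, then the
#' optional x-flip. Precision, channel, frame and photons are untouched.
#'
#' @param tab a `loc_table`.
#' @param t a `rigid_transform`.
#' @return the transformed `loc_table`.
#' @export
apply_transform <- function(tab, t) {
  validate_loc_table(tab)
  stopifnot(inherits(t, "rigid_transform"))
  x <- tab$x + t$dx
  y <- tab$y + t$dy
  ct <- cos(t$theta); st <- sin(t$theta)
  xr <- ct * x - st * y
  yr <- st * x + ct * y
  if (t$flip_x) xr <- -xr
  out <- tab
  out$x <- xr
  out$y <- yr
  out
}

#' Feature-based alignment of a single particle
#'
#' Determines the rigid transform that brings a particle (one ROI's
#' localizations) into canonical pose using its reference channel:
#' the centre of mass moves to the origin; the major principal axis of
#' the coordinate covariance is rotated onto the x-axis; and the side
#' carrying more mass (localization count, or photon sum when photon
#' counts are present) is oriented to the left (`x < 0`), matching the
#' highest-intensity-left display convention. The covariance estimator
#' acts on the localizations directly, so the result does not depend on
#' any rendering pixel grid.
#'
#' With the default `resolve_y = FALSE` the rotation is restricted to the
#' principal branch and only the left/right ambiguity is fixed; the
#' mirror ambiguity about the x-axis remains. `resolve_y = TRUE`
#' additionally applies a deterministic top-heavy rule, selecting among
#' the four candidate poses (theta or theta + pi, flipped or not) the
#' left-heavy one whose upper half-plane carries the larger mass: this
#' canonicalizes the pose completely, so identical particles under any
#' rigid motion or mirror land on identical poses.
#'
#' Particles whose reference-channel elongation is below 1.1 have a
#' noise-dominated principal axis; they are processed but flagged with
#' attribute `"orientation_unreliable"`.
#'
#' @param tab a `loc_table` for one particle.
#' @param reference_channel channel id used to derive the transform.
#' @param resolve_y logical; apply the top-heavy rule (see Details).
#' @return A `rigid_transform`.
#' @export
compute_alignment <- function(tab, reference_channel = 1L,
                              resolve_y = FALSE) {
  validate_loc_table(tab)
  ref <- tab[tab$channel == reference_channel, , drop = FALSE]
  if (nrow(ref) < 2L)
    stop("alignment error: reference channel ", reference_channel,
         " has fewer than 2 localizations")
  w <- if (all(!is.na(ref$photons))) ref$photons else rep(1, nrow(ref))
  sw <- sum(w)
  cx <- sum(w * ref$x) / sw
  cy <- sum(w * ref$y) / sw
  dx <- ref$x - cx; dy <- ref$y - cy
  cov <- matrix(c(sum(w * dx^2), sum(w * dx * dy),
                  sum(w * dx * dy), sum(w * dy^2)), 2L) / sw
  ev <- eigen(cov, symmetric = TRUE)
  lam <- ev$values
  if (lam[1L] <= 1e-12 * max(1, cx^2 + cy^2))
    stop("alignment error: degenerate covariance (coincident reference ",
         "localizations)")
  v <- ev$vectors[, 1L]
  alpha <- atan2(v[2L], v[1L])
  if (alpha <= -pi / 2) alpha <- alpha + pi
  if (alpha > pi / 2) alpha <- alpha - pi
  theta <- -alpha

  ct <- cos(theta); st <- sin(theta)
  px <- ct * dx - st * dy
  py <- st * dx + ct * dy
  ## half-plane mass with a continuous tie-break: exactly balanced counts
  ## (possible with even n) fall back to the per-side second moment,
  ## which is unconstrained (first moments vanish by centring) and agrees
  ## across rigid copies of the same point set
  heavier <- function(wa, wb, va, vb) {
    if (sum(wa) != sum(wb)) sum(wa) > sum(wb)
    else sum(wa * va^2) > sum(wb * vb^2)
  }
  right_heavy <- heavier(w[px > 0], w[px < 0], px[px > 0], px[px < 0])

  if (!resolve_y) {
    out <- rigid_transform(-cx, -cy, theta, right_heavy)
  } else {
    ## four candidate poses (theta or theta + pi, flipped or not); the
    ## left-heavy pair survives, then the top-heavy rule picks the one
    ## whose upper half carries more mass; both left-heavy candidates
    ## keep y = py or flip it, so deciding on py suffices
    top_heavy <- heavier(w[py > 0], w[py < 0], py[py > 0], py[py < 0])
    if (!right_heavy) {
      pick <- if (top_heavy) list(theta = theta, flip = FALSE)
              else list(theta = theta + pi, flip = TRUE)        # (x, -y)
    } else {
      pick <- if (top_heavy) list(theta = theta, flip = TRUE)   # (-x, y)
              else list(theta = theta + pi, flip = FALSE)       # (-x, -y)
    }
    th <- pick$theta
    if (th > pi) th <- th - 2 * pi
    out <- rigid_transform(-cx, -cy, th, pick$flip)
  }
  if (lam[2L] > 0 && sqrt(lam[1L] / lam[2L]) < 1.1)
    attr(out, "orientation_unreliable") <- TRUE
  out
}

#' Template-free particle averaging
#'
#' Aligns every particle (ROI) of a collection by its reference channel
#' -- centre of mass to the origin, major axis onto x, heavier side left
#' -- applies each particle's transform to all of its channels, and
#' merges. The merged structure can be rendered directly
#' (`"merged_render"`: one KDE of the pooled localizations) or as the
#' pixel-wise mean of per-particle renders (`"mean_of_renders"`).
#' Particles that fail alignment (degenerate reference covariance) are
#' skipped and reported.
#'
#' @param rois a `roi_collection` (one table per particle) or a plain
#'   list of `loc_table`.
#' @param reference_channel channel id driving the alignment.
#' @param geometry shared `image_geometry` centred at the origin; derived
#'   from the aligned data when `NULL`.
#' @param render_mode `"merged_render"` (default) or `"mean_of_renders"`.
#' @param bandwidth KDE bandwidth (nm) or `"auto"`.
#' @param resolve_y passed to [compute_alignment()].
#' @param pixel_size nm per pixel for the derived geometry.
#' @return An object of class `aligned_particles`: list with `particles`
#'   (transformed tables), `transforms` (data frame: particle, dx, dy,
#'   theta, flip_x), `merged` (pooled `loc_table` with a `particle`
#'   column), `mean_image` (a `rendered_image`) and `skipped` (names of
#'   particles that failed alignment).
#' @export
average_particles <- function(rois, reference_channel = 1L, geometry = NULL,
                              render_mode = c("merged_render",
                                              "mean_of_renders"),
                              bandwidth = "auto", resolve_y = FALSE,
                              pixel_size = 5) {
  render_mode <- match.arg(render_mode)
  tables <- if (inherits(rois, "roi_collection")) rois$tables else rois
  if (is.null(names(tables)) || any(names(tables) == ""))
    names(tables) <- sprintf("particle_%03d", seq_along(tables))
  aligned <- list()
  tf <- NULL
  skipped <- character(0)
  for (nm in names(tables)) {
    t_k <- tryCatch(compute_alignment(tables[[nm]], reference_channel,
                                      resolve_y = resolve_y),
                    error = function(e) e)
    if (inherits(t_k, "error")) {
      skipped <- c(skipped, nm)
      next
    }
    aligned[[nm]] <- apply_transform(tables[[nm]], t_k)
    tf <- rbind(tf, data.frame(particle = nm, dx = t_k$dx, dy = t_k$dy,
                               theta = t_k$theta, flip_x = t_k$flip_x,
                               stringsAsFactors = FALSE))
  }
  if (length(aligned) == 0L)
    stop("average_particles: no particle passed alignment")

  merged <- do.call(rbind, lapply(names(aligned), function(nm) {
    df <- as.data.frame(aligned[[nm]])
    df$particle <- nm
    df
  }))
  rownames(merged) <- NULL
  class(merged) <- c("loc_table", "data.frame")

  if (is.null(geometry)) {
    h0 <- if (identical(bandwidth, "auto")) mean(merged$precision)
          else as.numeric(bandwidth)
    ext <- max(abs(merged$x), abs(merged$y)) + 5 * h0
    npx <- 2L * as.integer(ceiling(ext / pixel_size))
    geometry <- image_geometry(-npx / 2 * pixel_size, -npx / 2 * pixel_size,
                               pixel_size, npx, npx)
  }
  if (render_mode == "merged_render") {
    mean_image <- render_kde(merged, geometry, bandwidth = bandwidth)
  } else {
    acc <- NULL
    for (ptab in aligned) {
      r <- render_kde(ptab, geometry, bandwidth = bandwidth)
      acc <- if (is.null(acc)) r$pixels else acc + r$pixels
    }
    mean_image <- rendered_image(acc / length(aligned), geometry, "kde",
                                 density_units = "localizations/um^2")
  }
  structure(list(particles = aligned, transforms = tf, merged = merged,
                 mean_image = mean_image, skipped = skipped),
            class = "aligned_particles")
}

#' @export
print.aligned_particles <- function(x, ...) {
  cat(sprintf("<aligned_particles> %d particle(s) aligned, %d skipped, %d pooled localizations\n",
              length(x$particles), length(x$skipped), nrow(x$merged)))
  invisible(x)
}
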