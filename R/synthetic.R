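## Synthetic ground-truthed SMLM data.
##
## The generators emulate a dSTORM-like field: isotropic Gaussian clusters
## of localizations over uniform background noise, with localization
## precisions drawn from a lognormal distribution (median 10 nm,
## sigma_log 0.3 -- typical of dSTORM with 10-20 nm resolution). They do
## NOT simulate blinking kinetics, drift, multi-frame emitters or camera
## noise.

## evaluate expr after set.seed(seed), restoring the caller's RNG state
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv(), inherits = FALSE) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  expr
}

.sample_precision <- function(n, meanlog = log(10), sdlog = 0.3) {
  stats::rlnorm(n, meanlog = meanlog, sdlog = sdlog)
}

#' Sample one isotropic Gaussian cluster of localizations
#'
#' Draws `n` points from an isotropic bivariate normal ("circular"
#' cluster) and attaches lognormal localization precisions. Uses the
#' current RNG state; seed upstream (or via [make_s2_testset()]) for
#' reproducibility.
#'
#' @param n number of localizations, >= 0.
#' @param center length-2 cluster centre (nm).
#' @param sd cluster standard deviation (nm), > 0.
#' @param shape `"gaussian"` (default) or `"disc"` (uniform disc of
#'   radius `2 * sd`).
#' @param precision_meanlog,precision_sdlog lognormal precision
#'   parameters.
#' @return A `loc_table` of `n` rows.
#' @export
sample_cluster <- function(n, center = c(0, 0), sd = 25,
                           shape = c("gaussian", "disc"),
                           precision_meanlog = log(10),
                           precision_sdlog = 0.3) {
  shape <- match.arg(shape)
  stopifnot(n >= 0, sd > 0)
  if (n == 0L) return(loc_table())
  if (shape == "gaussian") {
    x <- stats::rnorm(n, center[1L], sd)
    y <- stats::rnorm(n, center[2L], sd)
  } else {
    r <- 2 * sd * sqrt(stats::runif(n))
    a <- stats::runif(n, 0, 2 * pi)
    x <- center[1L] + r * cos(a)
    y <- center[2L] + r * sin(a)
  }
  loc_table(x, y, .sample_precision(n, precision_meanlog, precision_sdlog))
}

#' Sample uniform background noise localizations
#'
#' `n` i.i.d. uniform points in the square `[0, field_size)^2`,
#' emulating spurious localizations.
#'
#' @param n number of noise localizations, >= 0.
#' @param field_size field edge length (nm).
#' @param precision_meanlog,precision_sdlog lognormal precision
#'   parameters.
#' @return A `loc_table` of `n` rows.
#' @export
sample_uniform_noise <- function(n, field_size = 3000,
                                 precision_meanlog = log(10),
                                 precision_sdlog = 0.3) {
  stopifnot(n >= 0, field_size > 0)
  if (n == 0L) return(loc_table())
  loc_table(stats::runif(n, 0, field_size), stats::runif(n, 0, field_size),
            .sample_precision(n, precision_meanlog, precision_sdlog))
}

#' Configuration of the synthetic cluster benchmark
#'
#' Defaults reproduce the benchmark composition used throughout the test
#' suite: six isolated circular clusters of 50 localizations, one
#' component of 100 localizations made of two overlapping clusters, and
#' 300 uniformly distributed noise localizations (700 rows in total).
#' The geometry (3000 nm field, 25 nm cluster spread, 60 nm overlap
#' offset, 400 nm minimum centre separation) is this package's choice of
#' a realistic dSTORM scale.
#'
#' @param field_size field edge length (nm).
#' @param n_isolated_clusters number of isolated clusters.
#' @param n_per_cluster localizations per isolated cluster.
#' @param cluster_sd cluster standard deviation (nm).
#' @param n_overlap_total localizations in the overlap component (split
#'   evenly over its two sub-clusters).
#' @param overlap_offset distance between the overlapping sub-cluster
#'   centres (nm); must stay below `4 * cluster_sd` so they genuinely
#'   overlap.
#' @param n_noise uniform noise localizations.
#' @param min_center_separation minimum pairwise distance between
#'   component centres (nm).
#' @param precision_meanlog,precision_sdlog lognormal precision
#'   parameters.
#' @param seed RNG seed.
#' @return A list of class `s2_config`.
#' @export
s2_config <- function(field_size = 3000, n_isolated_clusters = 6,
                      n_per_cluster = 50, cluster_sd = 25,
                      n_overlap_total = 100, overlap_offset = 60,
                      n_noise = 300, min_center_separation = 400,
                      precision_meanlog = log(10), precision_sdlog = 0.3,
                      seed = 1L) {
  cfg <- list(field_size = field_size,
              n_isolated_clusters = as.integer(n_isolated_clusters),
              n_per_cluster = as.integer(n_per_cluster),
              cluster_sd = cluster_sd,
              n_overlap_total = as.integer(n_overlap_total),
              overlap_offset = overlap_offset,
              n_noise = as.integer(n_noise),
              min_center_separation = min_center_separation,
              precision_meanlog = precision_meanlog,
              precision_sdlog = precision_sdlog,
              seed = seed)
  stopifnot(cfg$n_isolated_clusters >= 0, cfg$n_per_cluster >= 0,
            cfg$n_overlap_total >= 0, cfg$n_noise >= 0,
            cfg$overlap_offset < 4 * cfg$cluster_sd)
  class(cfg) <- "s2_config"
  cfg
}

#' Generate the ground-truthed cluster benchmark
#'
#' Emits a localization table plus aligned per-row ground truth: isolated
#' clusters carry components 1..6, the two overlapping sub-clusters share
#' component 7 (they form one connected structure), and noise is
#' component 0. Component counts equal the configuration exactly. The
#' output is a pure function of the configuration (including its seed).
#'
#' @param config an [s2_config()].
#' @return A list with `locs` (a `loc_table`) and `truth` (data frame of
#'   class `ground_truth` with columns `id`, `component`,
#'   `component_kind`).
#' @examples
#' set <- make_s2_testset(s2_config(seed = 7))
#' table(set$truth$component)
#' @export
make_s2_testset <- function(config = s2_config()) {
  stopifnot(inherits(config, "s2_config"))
  .with_seed(config$seed, {
    n_centers <- config$n_isolated_clusters + 1L   # + the overlap pair
    margin <- min(config$min_center_separation / 2, config$field_size / 4)
    centers <- matrix(NA_real_, 0L, 2L)
    attempts <- 0L
    while (nrow(centers) < n_centers) {
      attempts <- attempts + 1L
      if (attempts > 20000L)
        stop("could not place cluster centres at the requested separation; ",
             "increase field_size or lower min_center_separation")
      cand <- stats::runif(2, margin, config$field_size - margin)
      if (nrow(centers) == 0L ||
          all(sqrt(rowSums(sweep(centers, 2L, cand)^2)) >=
              config$min_center_separation))
        centers <- rbind(centers, cand)
    }

    parts <- list(); comp <- integer(0); kind <- character(0)
    for (k in seq_len(config$n_isolated_clusters)) {
      tabk <- sample_cluster(config$n_per_cluster, centers[k, ],
                             config$cluster_sd,
                             precision_meanlog = config$precision_meanlog,
                             precision_sdlog = config$precision_sdlog)
      parts[[length(parts) + 1L]] <- tabk
      comp <- c(comp, rep(k, nrow(tabk)))
      kind <- c(kind, rep("cluster", nrow(tabk)))
    }
    ## overlap pair: two sub-clusters around the last centre
    ang <- stats::runif(1, 0, 2 * pi)
    off <- config$overlap_offset / 2 * c(cos(ang), sin(ang))
    ov_center <- centers[n_centers, ]
    n_a <- config$n_overlap_total %/% 2L
    n_b <- config$n_overlap_total - n_a
    for (nn in c(n_a, n_b)) {
      tabk <- sample_cluster(nn, ov_center + off, config$cluster_sd,
                             precision_meanlog = config$precision_meanlog,
                             precision_sdlog = config$precision_sdlog)
      parts[[length(parts) + 1L]] <- tabk
      comp <- c(comp, rep(config$n_isolated_clusters + 1L, nrow(tabk)))
      kind <- c(kind, rep("overlap_pair", nrow(tabk)))
      off <- -off
    }
    noise <- sample_uniform_noise(config$n_noise, config$field_size,
                                  config$precision_meanlog,
                                  config$precision_sdlog)
    parts[[length(parts) + 1L]] <- noise
    comp <- c(comp, rep(0L, nrow(noise)))
    kind <- c(kind, rep("noise", nrow(noise)))

    df <- do.call(rbind, lapply(parts, as.data.frame))
    locs <- loc_table(df$x, df$y, df$precision, df$channel, df$frame,
                      df$photons)
    truth <- data.frame(id = locs$id, component = as.integer(comp),
                        component_kind = kind, stringsAsFactors = FALSE)
    class(truth) <- c("ground_truth", "data.frame")
    list(locs = locs, truth = truth)
  })
}

#' Generate asymmetric elongated particles under recorded rigid motions
#'
#' Builds `k` copies of an elongated particle in canonical frame: y is
#' Gaussian with spread `width_sd`, and x is a zero-mean two-lobe
#' half-normal mixture with total spread `length_sd` in which a fraction
#' `left_fraction` of the points lies at `x < 0` (a narrow dense left
#' lobe balanced by a wide sparse right lobe, so the particle is centred
#' yet count-asymmetric). Each copy is then
#' applies to each a recorded random rotation, translation and (with
#' probability 1/2, when `mirror = TRUE`) a mirror. Used to validate that
#' feature-based alignment recovers the canonical pose.
#'
#' The forward motion of particle `p` is
#' `q = R(theta_true) * M^mirrored * p + (tx, ty)` with `M` the x-flip.
#'
#' @param k number of particles.
#' @param n_per localizations per particle.
#' @param length_sd,width_sd canonical major/minor standard deviations
#'   (nm), `length_sd > width_sd`.
#' @param left_fraction fraction of points at `x < 0` in canonical frame,
#'   in `[0.5, 1)`.
#' @param field_size ROI edge length (nm); motions keep centres near the
#'   ROI middle.
#' @param mirror allow random mirroring.
#' @param seed RNG seed.
#' @param precision_meanlog,precision_sdlog lognormal precision
#'   parameters.
#' @return A list with `rois` (a `roi_collection`), `canonical` (list of
#'   canonical-frame `loc_table`), `truth_transforms` (data frame:
#'   particle, theta, tx, ty, mirrored) and `truth` (`ground_truth` with
#'   the particle id as component).
#' @export
make_elongated_particles <- function(k = 10, n_per = 300, length_sd = 60,
                                     width_sd = 20, left_fraction = 0.7,
                                     field_size = 2000, mirror = TRUE,
                                     seed = 1L,
                                     precision_meanlog = log(10),
                                     precision_sdlog = 0.3) {
  stopifnot(length_sd > width_sd, left_fraction >= 0.5, left_fraction < 1)
  .with_seed(seed, {
    names_p <- sprintf("particle_%03d", seq_len(k))
    canonical <- vector("list", k); names(canonical) <- names_p
    tables <- vector("list", k); names(tables) <- names_p
    tf <- data.frame(particle = names_p, theta = stats::runif(k, -pi, pi),
                     tx = field_size / 2 + stats::runif(k, -field_size / 8,
                                                        field_size / 8),
                     ty = field_size / 2 + stats::runif(k, -field_size / 8,
                                                        field_size / 8),
                     mirrored = if (mirror) stats::runif(k) < 0.5
                                else rep(FALSE, k),
                     stringsAsFactors = FALSE)
    comp <- integer(0)
    ## two half-normal lobes: a fraction left_fraction of points on the
    ## left with scale sd_l, the rest on the right with the wider scale
    ## sd_r = left_fraction/(1-left_fraction) * sd_l, so the distribution
    ## has mean zero (the canonical particle is centred), total standard
    ## deviation length_sd, and the left lobe keeps its point majority
    ## even about the centre of mass
    f <- left_fraction
    sd_l <- length_sd * sqrt((1 - f) / f)
    sd_r <- f / (1 - f) * sd_l
    for (p in seq_len(k)) {
      left <- stats::runif(n_per) < f
      x <- ifelse(left, -abs(stats::rnorm(n_per, 0, sd_l)),
                  abs(stats::rnorm(n_per, 0, sd_r)))
      y <- stats::rnorm(n_per, 0, width_sd)
      canon <- loc_table(x, y,
                         .sample_precision(n_per, precision_meanlog,
                                           precision_sdlog))
      canonical[[p]] <- canon
      xm <- if (tf$mirrored[p]) -canon$x else canon$x
      ct <- cos(tf$theta[p]); st <- sin(tf$theta[p])
      moved <- canon
      moved$x <- ct * xm - st * canon$y + tf$tx[p]
      moved$y <- st * xm + ct * canon$y + tf$ty[p]
      tables[[p]] <- moved
      comp <- c(comp, rep(p, n_per))
    }
    rois <- roi_set(names_p, rep(0, k), rep(0, k),
                    rep(field_size, k), rep(field_size, k))
    truth <- data.frame(id = seq_along(comp), component = comp,
                        component_kind = rep("particle", length(comp)),
                        stringsAsFactors = FALSE)
    class(truth) <- c("ground_truth", "data.frame")
    list(rois = structure(list(rois = rois, tables = tables),
                          class = "roi_collection"),
         canonical = canonical,
         truth_transforms = tf,
         truth = truth)
  })
}
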