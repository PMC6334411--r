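# a small canonical particle: centred, major axis on x, left-heavy,
# coordinate covariance exactly diagonal
canonical_particle <- function() {
  loc_table(x = c(-5, -1, 6), y = c(0.7, -1.1, 0.4), precision = 10)
}

test_that("points on a 45-degree line are centred and mapped onto the x-axis", {
  t <- seq(-50, 50, by = 10)
  tab <- loc_table(100 + t, 100 + t, precision = 10)
  tr <- compute_alignment(tab)
  out <- apply_transform(tab, tr)
  expect_true(all(abs(out$y) < 1e-6))
  expect_equal(mean(out$x), 0, tolerance = 1e-9)
})

test_that("an already-canonical particle yields the identity transform", {
  tab <- canonical_particle()
  tr <- compute_alignment(tab)
  expect_equal(tr$dx, 0)
  expect_equal(tr$dy, 0)
  expect_equal(tr$theta, 0)
  expect_false(tr$flip_x)
})

test_that("a y-axis mirrored canonical particle is flipped back (involution)", {
  tab <- canonical_particle()
  mir <- loc_table(-tab$x, tab$y, tab$precision)
  tr <- compute_alignment(mir)
  expect_true(tr$flip_x)
  out <- apply_transform(mir, tr)
  expect_equal(out$x, tab$x, tolerance = 1e-9)
  expect_equal(out$y, tab$y, tolerance = 1e-9)
})

test_that("rigid transforms are isometries and leave annotations untouched", {
  withr::local_seed(81)
  tab <- random_loc_table(40, field = 500)
  tr <- rigid_transform(dx = -123.4, dy = 55, theta = 0.8, flip_x = TRUE)
  out <- apply_transform(tab, tr)
  d0 <- as.matrix(dist(cbind(tab$x, tab$y)))
  d1 <- as.matrix(dist(cbind(out$x, out$y)))
  expect_equal(d1, d0, tolerance = 1e-9)
  expect_identical(out$precision, tab$precision)
  expect_identical(out$channel, tab$channel)
  expect_identical(out$id, tab$id)

  ident <- apply_transform(tab, rigid_transform())
  expect_equal(as.data.frame(ident), as.data.frame(tab))
  pt <- apply_transform(loc_table(0, 0, 10), rigid_transform(dx = 7))
  expect_equal(c(pt$x, pt$y), c(7, 0))
})

test_that("alignment is idempotent: a second pass is the identity", {
  withr::local_seed(82)
  gen <- make_elongated_particles(k = 5, n_per = 200, seed = 82)
  for (p in seq_len(5)) {
    once <- apply_transform(gen$rois$tables[[p]],
                            compute_alignment(gen$rois$tables[[p]]))
    again <- compute_alignment(once)
    expect_lt(abs(again$dx), 1e-6)
    expect_lt(abs(again$dy), 1e-6)
    expect_lt(min(abs(again$theta), pi - abs(again$theta)), 1e-6)
    expect_false(again$flip_x)
    # canonical invariants: centroid at origin, diagonal covariance
    expect_equal(mean(once$x), 0, tolerance = 1e-9)
    expect_lt(abs(mean((once$x - mean(once$x)) * (once$y - mean(once$y)))) /
                stats::var(once$x), 1e-6)
    # heavier side left
    expect_gte(sum(once$x < 0), sum(once$x > 0))
  }
})

test_that("recorded rigid motions and mirrors are inverted exactly", {
  gen <- make_elongated_particles(k = 12, n_per = 250, seed = 83)
  expect_true(any(gen$truth_transforms$mirrored))   # mirrors exercised
  for (p in seq_len(12)) {
    canon <- apply_transform(gen$canonical[[p]],
                             compute_alignment(gen$canonical[[p]],
                                               resolve_y = TRUE))
    moved <- apply_transform(gen$rois$tables[[p]],
                             compute_alignment(gen$rois$tables[[p]],
                                               resolve_y = TRUE))
    expect_lt(max(abs(canon$x - moved$x), abs(canon$y - moved$y)), 1e-6)
  }
})

test_that("round particles are flagged orientation-unreliable but processed", {
  withr::local_seed(84)
  round_tab <- sample_cluster(4000, c(50, 50), 30)
  tr <- compute_alignment(round_tab)
  expect_true(isTRUE(attr(tr, "orientation_unreliable")))
  elong <- sample_cluster(400, c(0, 0), 30)
  elong$x <- elong$x * 3
  expect_null(attr(compute_alignment(elong), "orientation_unreliable"))
})

test_that("coincident reference localizations raise an alignment error", {
  tab <- loc_table(rep(5, 4), rep(5, 4), precision = 10)
  expect_error(compute_alignment(tab), "degenerate")
  expect_error(compute_alignment(loc_table(1, 1, 10)), "fewer than 2")
})

test_that("averaging two identical canonical particles is idempotent", {
  tab <- canonical_particle()
  g <- image_geometry(-50, -50, 5, 20, 20)
  avg <- average_particles(list(a = tab, b = tab), geometry = g,
                           render_mode = "mean_of_renders", bandwidth = 10)
  single <- render_kde(apply_transform(tab, compute_alignment(tab)), g,
                       bandwidth = 10)
  expect_equal(avg$mean_image$pixels, single$pixels)
  expect_equal(nrow(avg$merged), 6L)
  expect_true("particle" %in% names(avg$merged))
})

test_that("particle averaging recovers structure and reports skips", {
  gen <- make_elongated_particles(k = 10, n_per = 300, left_fraction = 0.7,
                                  seed = 85)
  tables <- gen$rois$tables
  tables$degenerate <- loc_table(rep(1, 5), rep(1, 5), precision = 10)
  avg <- average_particles(tables, resolve_y = TRUE)
  expect_equal(length(avg$particles), 10L)
  expect_equal(avg$skipped, "degenerate")
  # every aligned particle keeps ~70% of its mass on the left
  lf <- vapply(avg$particles, function(t) mean(t$x < 0), 0)
  expect_true(all(abs(lf - 0.7) < 0.1))
  # pooled major axis lies along x
  f <- cluster_features(avg$merged, rep(1L, nrow(avg$merged)))
  expect_lt(abs(f$orientation) * 180 / pi, 2)
  expect_error(average_particles(list(only = tables$degenerate)),
               "no particle")
})
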