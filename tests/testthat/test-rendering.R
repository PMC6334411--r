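test_that("Gaussian render matches the closed-form kernel at pixel centres", {
  g <- image_geometry(0, 0, pixel_size = 5, width = 21, height = 21)
  # localization exactly at the centre of pixel (10, 10)
  tab <- loc_table(x = 52.5, y = 52.5, precision = 10)
  img <- render_gaussian(tab, g)
  expect_equal(img$pixels[11, 11], 1 / (2 * pi * 100) * 25, tolerance = 1e-12)
  # off-centre pixel at (dx, dy) = (10, 5) nm
  expect_equal(img$pixels[12, 13],
               25 / (2 * pi * 100) * exp(-(100 + 25) / 200),
               tolerance = 1e-12)
  # empty table renders a zero image
  z <- render_gaussian(loc_table(), g)
  expect_true(all(z$pixels == 0))
})

test_that("Gaussian rendering is linear in the table", {
  withr::local_seed(21)
  g <- image_geometry(0, 0, 5, 40, 40)
  t1 <- random_loc_table(15, field = 200)
  t2 <- random_loc_table(10, field = 200)
  both <- loc_table(c(t1$x, t2$x), c(t1$y, t2$y),
                    c(t1$precision, t2$precision))
  r12 <- render_gaussian(both, g)$pixels
  expect_equal(r12, render_gaussian(t1, g)$pixels +
                    render_gaussian(t2, g)$pixels, tolerance = 1e-12)
  # duplicated localization doubles the image
  dup <- loc_table(rep(t1$x, 2), rep(t1$y, 2), rep(t1$precision, 2))
  expect_equal(render_gaussian(dup, g)$pixels,
               2 * render_gaussian(t1, g)$pixels)
})

test_that("KDE is count-normalized: mass equals N and units are per um^2", {
  h <- 10
  g <- image_geometry(0, 0, 5, 60, 60)
  tab <- loc_table(rep(150, 5), rep(150, 5), rep(8, 5))
  img <- render_kde(tab, g, bandwidth = h)
  mass <- sum(img$pixels) * (g$pixel_size / 1000)^2
  expect_equal(mass, 5, tolerance = 1e-3)
  expect_equal(img$density_units, "localizations/um^2")

  # single point: value at its own pixel is the kernel peak density
  one <- loc_table(152.5, 152.5, 8)
  i1 <- render_kde(one, g, bandwidth = h)
  expect_equal(i1$pixels[31, 31], 1e6 / (2 * pi * h^2), tolerance = 1e-12)

  # duplicating every row doubles every pixel
  dup <- loc_table(rep(tab$x, 2), rep(tab$y, 2), rep(tab$precision, 2))
  expect_equal(render_kde(dup, g, bandwidth = h)$pixels, 2 * img$pixels)
})

test_that("KDE pixel values are invariant to row order", {
  withr::local_seed(22)
  tab <- random_loc_table(40, field = 200)
  g <- image_geometry(0, 0, 5, 40, 40)
  perm <- sample(nrow(tab))
  shuf <- loc_table(tab$x[perm], tab$y[perm], tab$precision[perm])
  expect_equal(render_kde(shuf, g, bandwidth = 12)$pixels,
               render_kde(tab, g, bandwidth = 12)$pixels)
})

test_that("rendering is translation-equivariant (bit-identical on exact shifts)", {
  withr::local_seed(23)
  # integer-nm coordinates so the shifted inputs are exactly representable
  tab <- loc_table(sample(50:250, 30), sample(50:250, 30),
                   sample(8:20, 30, TRUE))
  g <- image_geometry(0, 0, 5, 60, 60)
  shift <- c(1024, -512)
  tab2 <- loc_table(tab$x + shift[1], tab$y + shift[2], tab$precision)
  g2 <- image_geometry(shift[1], shift[2], 5, 60, 60)
  expect_identical(render_gaussian(tab2, g2)$pixels,
                   render_gaussian(tab, g)$pixels)
  expect_identical(render_kde(tab2, g2, bandwidth = 10)$pixels,
                   render_kde(tab, g, bandwidth = 10)$pixels)
})

test_that("auto bandwidth is the mean localization precision", {
  tab <- loc_table(c(100, 120), c(100, 120), c(10, 30))
  g <- image_geometry(0, 0, 5, 44, 44)
  img <- render_kde(tab, g)
  expect_equal(attr(img, "bandwidth"), 20)
})

test_that("channel composites mix additively and clip", {
  g <- image_geometry(0, 0, 5, 10, 10)
  a <- matrix(0, 10, 10); a[2, 2] <- 4
  b <- matrix(0, 10, 10); b[8, 8] <- 2
  ia <- rendered_image(a, g, "gaussian")
  ib <- rendered_image(b, g, "gaussian")

  green <- composite_channels(list(ia), colors = "green")
  expect_equal(green[2, 2, ], c(0, 1, 0))   # pure green, self-normalized

  two <- composite_channels(list(ia, ib), colors = c("green", "red"))
  expect_equal(two[2, 2, ], c(0, 1, 0))     # disjoint support: no mixing
  expect_equal(two[8, 8, ], c(1, 0, 0))

  yellow <- composite_channels(list(ia, ia), colors = c("red", "green"))
  expect_equal(yellow[2, 2, ], c(1, 1, 0))  # identical images mix to yellow

  g2 <- image_geometry(0, 0, 5, 9, 9)
  expect_error(composite_channels(list(ia, rendered_image(matrix(0, 9, 9),
                                                          g2, "gaussian"))),
               "geometries differ")
})

test_that("float TIFFs round-trip pixel values and calibration exactly", {
  withr::local_seed(24)
  tab <- random_loc_table(20, field = 150)
  g <- image_geometry(-10, -20, 5, 40, 40)
  img <- render_kde(tab, g, bandwidth = 10)
  f <- withr::local_tempfile(fileext = ".tif")
  write_image(img, f)
  back <- read_image(f)
  # float32 storage: exact for values that fit in single precision
  expect_equal(back$pixels, matrix(as.numeric(img$pixels), nrow(img$pixels)),
               tolerance = 1e-6)
  expect_equal(back$geometry$pixel_size, 5)
  expect_equal(back$geometry$x0, -10)
  expect_equal(back$geometry$y0, -20)
  expect_equal(back$mode, "kde")

  zero <- rendered_image(matrix(0, 8, 8), image_geometry(0, 0, 5, 8, 8),
                         "gaussian")
  f2 <- withr::local_tempfile(fileext = ".tif")
  write_image(zero, f2)
  expect_true(all(read_image(f2)$pixels == 0))
})

test_that("label images round-trip through 16-bit TIFF", {
  g <- image_geometry(0, 0, 5, 12, 12)
  lab <- matrix(0L, 12, 12); lab[3:5, 3:5] <- 1L; lab[9:10, 9:11] <- 2L
  img <- rendered_image(lab, g, "labels")
  f <- withr::local_tempfile(fileext = ".tif")
  write_image(img, f)
  back <- read_image(f)
  expect_equal(back$pixels, matrix(as.numeric(lab), 12), tolerance = 1e-9)
})

test_that("scatter export writes deterministic files and validates fields", {
  tab <- loc_table(c(0, 10, 20), c(0, 5, 1), c(8, 10, 12),
                   channel = c(1, 1, 2))
  f <- withr::local_tempfile(fileext = ".png")
  scatter_export(tab, f)
  expect_true(file.exists(f) && file.size(f) > 0)
  expect_error(scatter_export(tab, f, size_by = "nope"), "size_by")
  f2 <- withr::local_tempfile(fileext = ".png")
  scatter_export(loc_table(), f2)   # empty axes still written
  expect_true(file.exists(f2) && file.size(f2) > 0)
})
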