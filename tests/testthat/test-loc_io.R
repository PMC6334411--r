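test_that("generic CSV import is an identity passthrough in nm", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("x,y,precision", "0,0,10", "5,5,12", "9,1,8"), f)
  tab <- read_locs(f, dialect = "generic", unit_scale = 1)
  expect_s3_class(tab, "loc_table")
  expect_equal(nrow(tab), 3L)
  expect_equal(tab$x, c(0, 5, 9))
  expect_equal(tab$precision, c(10, 12, 8))
  expect_equal(attr(tab, "n_rejected"), 0L)
})

test_that("ThunderSTORM headers are auto-mapped and unit_scale converts", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c('"x [nm]","y [nm]","uncertainty [nm]","sigma [nm]","frame"',
               "100.5,200.25,9.75,150,3",
               "300,400,12.5,160,4"), f)
  tab <- read_locs(f)
  expect_equal(tab$x, c(100.5, 300))
  expect_equal(tab$precision, c(9.75, 12.5))
  expect_equal(tab$frame, c(3L, 4L))

  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("x,y,precision", "0.1,0.2,0.01"), f2)
  um <- read_locs(f2, unit_scale = 1000)   # micrometre input
  expect_equal(um$x, 100)
  expect_equal(um$precision, 10)
})

test_that("malformed and invariant-violating rows are rejected with a count", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("x,y,precision", "1,1,10", "2,2,-5", "3,oops,8", "4,4,12"), f)
  expect_message(tab <- read_locs(f), "2 malformed")
  expect_equal(nrow(tab), 2L)
  expect_equal(attr(tab, "n_rejected"), 2L)
})

test_that("missing required columns and empty files raise clear errors", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("x,y", "1,2"), f)
  expect_error(read_locs(f), "precision")
  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines("x,y,precision", f2)
  expect_error(read_locs(f2), "empty")
})

test_that("write_locs / read_locs round-trips field values to 1e-9 nm", {
  withr::local_seed(11)
  for (rep in 1:100) {
    n <- sample(1:30, 1)
    tab <- loc_table(runif(n, 0, 3000), runif(n, 0, 3000),
                     runif(n, 1, 40), channel = sample(1:2, n, TRUE),
                     frame = sample(0:99, n, TRUE),
                     photons = round(runif(n, 100, 5000)))
    f <- tempfile(fileext = ".csv")
    write_locs(tab, f)
    back <- read_locs(f, dialect = "generic")
    expect_equal(back$x, tab$x, tolerance = 1e-12)
    expect_true(max(abs(back$x - tab$x), abs(back$y - tab$y),
                    abs(back$precision - tab$precision)) < 1e-9)
    expect_identical(back$channel, tab$channel)
    expect_identical(back$frame, tab$frame)
    unlink(f)
  }
  empty <- loc_table()
  f <- withr::local_tempfile(fileext = ".csv")
  write_locs(empty, f)
  expect_equal(length(readLines(f)), 1L)   # header only
})

test_that("filter_locs matches a brute-force row scan and preserves order", {
  tab <- loc_table(c(1, 2), c(1, 2), c(10, 30))
  expect_equal(nrow(filter_locs(tab, precision_max = 20)), 1L)
  expect_equal(nrow(filter_locs(tab, channel = 2)), 0L)

  withr::local_seed(5)
  big <- loc_table(runif(200, 0, 100), runif(200, 0, 100),
                   runif(200, 1, 40), channel = sample(1:3, 200, TRUE),
                   frame = sample(0:9, 200, TRUE))
  got <- filter_locs(big, precision_max = 25, channel = c(1, 3),
                     frame_range = c(2, 7), x_range = c(10, 90))
  keep <- big$precision <= 25 & big$channel %in% c(1, 3) &
    big$frame >= 2 & big$frame <= 7 & big$x >= 10 & big$x <= 90
  expect_identical(got$id, big$id[keep])
  # true predicate is the identity
  expect_identical(as.data.frame(filter_locs(big)), as.data.frame(big))
})

test_that("split_rois uses half-open membership and ROI-local coordinates", {
  tab <- loc_table(c(10, 100, 50), c(10, 100, 25), c(10, 10, 10))
  rois <- roi_set("a", 0, 0, 50, 50)
  coll <- split_rois(tab, rois)
  expect_equal(nrow(coll$tables$a), 1L)   # (50, 25) excluded: x == x_max
  expect_equal(coll$tables$a$x, 10)
  expect_equal(coll$tables$a$id, 1L)

  withr::local_seed(7)
  big <- random_loc_table(500, field = 1000)
  r <- roi_set(letters[1:5], runif(5, 0, 500), runif(5, 0, 500),
               runif(5, 600, 1000), runif(5, 600, 1000))
  coll <- split_rois(big, r)
  for (i in 1:5) {
    inside <- big$x >= r$x_min[i] & big$x < r$x_max[i] &
      big$y >= r$y_min[i] & big$y < r$y_max[i]
    expect_equal(nrow(coll$tables[[i]]), sum(inside))
    expect_true(all(coll$tables[[i]]$x >= 0 &
                    coll$tables[[i]]$x < r$x_max[i] - r$x_min[i]))
  }
})

test_that("non-overlapping ROIs never duplicate a localization", {
  withr::local_seed(8)
  tab <- random_loc_table(300, field = 100)
  r <- roi_set(c("q1", "q2", "q3", "q4"),
               c(0, 50, 0, 50), c(0, 0, 50, 50),
               c(50, 100, 50, 100), c(50, 50, 100, 100))
  coll <- split_rois(tab, r)
  ids <- unlist(lapply(coll$tables, function(t) t$id))
  expect_false(any(duplicated(ids)))
  expect_equal(length(ids), nrow(tab))   # the four quadrants tile the field
})

test_that("ROI files round-trip", {
  r <- roi_set(c("a", "b"), c(0, 10), c(0, 20), c(5, 30), c(5, 40))
  f <- withr::local_tempfile(fileext = ".csv")
  write_rois(r, f)
  back <- read_rois(f)
  expect_equal(as.data.frame(back), as.data.frame(r))
  expect_error(roi_set("bad", 10, 0, 5, 5), "x_min < x_max")
})
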