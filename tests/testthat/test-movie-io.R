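test_that("TIFF write/read round trip is lossless for counts and metadata", {
  sim <- vm_movie(rows = 5, cols = 7, n_beats = 2, noise_sd = 0.02,
                  digitize = TRUE, seed = 3)
  path <- tempfile(fileext = ".tif")
  write_movie(sim$movie, path)
  m2 <- read_movie(path, sub("[.]tif$", ".json", path))
  expect_identical(dim(m2$data), dim(sim$movie$data))
  expect_equal(m2$data, sim$movie$data)
  expect_identical(m2$frame_interval, sim$movie$frame_interval)
  expect_identical(m2$pixel_pitch, sim$movie$pixel_pitch)
  expect_equal(m2$stimulus_times, sim$movie$stimulus_times)
  expect_identical(m2$channel, "voltage")
})

test_that("raw binary reader recovers a camera dump exactly", {
  sim <- ca_movie(rows = 4, cols = 6, n_beats = 2, noise_sd = 0.02,
                  digitize = TRUE)
  path <- tempfile(fileext = ".bin")
  write_movie_raw(sim$movie, path)
  m2 <- read_movie(path, paste0(path, ".json"), format = "raw")
  expect_equal(m2$data, sim$movie$data)
  expect_identical(m2$channel, "calcium")
})

test_that("a known 3-frame stack is recovered value for value", {
  d <- array(c(1:12) * 100, c(3, 2, 2))
  mv <- mapping_movie(d, frame_interval = 2, pixel_pitch = 0.1)
  path <- tempfile(fileext = ".tif")
  write_movie(mv, path)
  m2 <- read_movie(path, sub("[.]tif$", ".json", path))
  expect_equal(m2$data, d)
})

test_that("missing or inconsistent metadata is reported by field name", {
  sim <- vm_movie(rows = 4, cols = 4, n_beats = 2)
  path <- tempfile(fileext = ".tif")
  write_movie(sim$movie, path)
  meta_path <- sub("[.]tif$", ".json", path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  broken <- meta[setdiff(names(meta), "frame_interval_ms")]
  bp <- tempfile(fileext = ".json")
  jsonlite::write_json(broken, bp, auto_unbox = TRUE)
  expect_error(read_movie(path, bp), "frame_interval_ms")
  meta$frames <- meta$frames + 5
  jsonlite::write_json(meta, bp, auto_unbox = TRUE)
  expect_error(read_movie(path, bp), "frame-count mismatch")
})

test_that("map CSVs are row-major, omit invalid pixels, and re-run stable", {
  m <- matrix(7, 4, 4)
  mask <- matrix(TRUE, 4, 4)
  mask[1, 1] <- FALSE
  out <- tempfile()
  write_maps(list(metric = m), mask, out)
  df <- read.csv(file.path(out, "metric.csv"))
  expect_equal(nrow(df), 15)
  expect_true(all(df$value == 7))
  expect_false(any(df$row == 0 & df$col == 0))
  expect_true(!is.unsorted(df$row))
  df2 <- read.csv(file.path(out, "metric.csv"))
  write_maps(list(metric = m), mask, out)
  expect_identical(df, read.csv(file.path(out, "metric.csv")))
  expect_error(write_maps(list(metric = m), matrix(FALSE, 4, 4), out),
               "empty mask")
  expect_error(write_maps(list(a = m, b = matrix(1, 3, 3)),
                          mask, out), "different grids")
})

test_that("isochrones of a noiseless planar wave are straight and 5 ms apart", {
  act <- matrix(rep(0:29, each = 30) * 2.5, 30, 30)  # 2.5 ms per column
  iso <- isochrones(act, 5)
  expect_gt(length(iso), 3)
  levels <- vapply(iso, function(l) l$level[1], numeric(1))
  expect_equal(sort(unique(round(diff(sort(unique(levels))), 9))), 5)
  for (l in iso) {
    # each contour is a vertical line: constant column, spanning rows
    expect_lt(diff(range(l$col)), 1e-9)
    expect_gt(diff(range(l$row)), 20)
  }
  # consecutive isochrones are evenly spaced in the image (2 px per 5 ms)
  cols <- vapply(iso, function(l) mean(l$col), numeric(1))
  expect_equal(diff(sort(cols)), rep(2, length(cols) - 1), tolerance = 1e-6)
})
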