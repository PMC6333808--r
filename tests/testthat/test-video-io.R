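test_that("frame_stack validates its invariants and keeps metadata", {
  arr <- array(runif(4 * 5 * 3), dim = c(4, 5, 3))
  fs <- frame_stack(arr, frame_rate = 16.5)
  expect_identical(dim(fs), c(4L, 5L, 3L))
  expect_equal(fs$frame_rate, 16.5)
  expect_equal(fs$pixel_size, 3.24)

  expect_error(frame_stack(array(1, dim = c(4, 5, 1))), "at least 2")
  expect_error(frame_stack(arr, frame_rate = 0), "positive")
  bad <- arr; bad[1] <- -1
  expect_error(frame_stack(bad), "non-negative")
  bad[1] <- NaN
  expect_error(frame_stack(bad), "finite")
})

test_that("write_stack/load_stack round trip is lossless for integer data", {
  set.seed(1)
  arr <- array(sample(0:65535, 16 * 16 * 5, replace = TRUE),
               dim = c(16, 16, 5))
  fs <- frame_stack(arr, frame_rate = 10)
  path <- withr::local_tempfile(fileext = ".tif")
  write_stack(fs, path, max_value = 65535)
  back <- load_stack(path, frame_rate = 10)
  expect_identical(dim(back), dim(fs))
  expect_equal(back$frames * 65535, fs$frames, tolerance = 1e-12)
  expect_equal(back$frame_rate, 10)
})

test_that("load_stack reads a directory of PNG frames in name order", {
  dir <- withr::local_tempdir()
  set.seed(2)
  mats <- lapply(1:4, function(i) matrix(runif(12 * 10), 12, 10))
  for (i in 1:4) {
    png::writePNG(mats[[i]], file.path(dir, sprintf("frame_%02d.png", i)))
  }
  fs <- load_stack(dir, frame_rate = 5)
  expect_identical(dim(fs), c(12L, 10L, 4L))
  # PNG quantizes to 8 bits; ordering must still be exact
  for (i in 1:4) {
    expect_equal(get_frame(fs, i), mats[[i]], tolerance = 1 / 255)
  }
})

test_that("load_stack reports unreadable, short and mismatched inputs", {
  expect_error(load_stack("/nonexistent/file.tif"), "no such file")

  junk <- withr::local_tempfile(fileext = ".tif")
  writeLines("not a tiff", junk)
  expect_error(load_stack(junk), "cannot parse")

  dir <- withr::local_tempdir()
  png::writePNG(matrix(0.5, 4, 4), file.path(dir, "a.png"))
  expect_error(load_stack(dir), "insufficient data")

  png::writePNG(matrix(0.5, 5, 4), file.path(dir, "b.png"))
  expect_error(load_stack(dir), "dimension mismatch")
})

test_that("multi-channel frames collapse to the channel mean", {
  dir <- withr::local_tempdir()
  rgb <- array(0, dim = c(4, 4, 3))
  rgb[, , 1] <- 0.2; rgb[, , 2] <- 0.4; rgb[, , 3] <- 0.9
  png::writePNG(rgb, file.path(dir, "a.png"))
  png::writePNG(rgb, file.path(dir, "b.png"))
  fs <- load_stack(dir, frame_rate = 2)
  expect_equal(unique(as.vector(fs$frames)), 0.5, tolerance = 1 / 255)
})

test_that("intensity tables round-trip as strict TSV", {
  tr1 <- intensity_trace(c(0, 0.5, 1), c(10, 20, 30), embryo_id = 1)
  tr2 <- intensity_trace(c(0, 0.5, 1), c(5.123456, 6.54321, 7 / 3),
                         embryo_id = 2)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_intensity_table(list(tr1, tr2), path)

  lines <- readLines(path)
  expect_length(lines, 4L)                     # header + 3 data rows
  expect_true(all(lengths(strsplit(lines, "\t", fixed = TRUE)) == 3L))

  back <- read_intensity_table(path)
  expect_length(back, 2L)
  rng <- diff(range(c(tr1$values, tr2$values)))
  expect_lt(max(abs(back[[1]]$values - tr1$values)), 1e-6 * rng)
  expect_lt(max(abs(back[[2]]$values - tr2$values)), 1e-6 * rng)
  expect_identical(back[[2]]$embryo_id, 2L)
})

test_that("intensity table writing rejects degenerate input", {
  path <- withr::local_tempfile(fileext = ".tsv")
  expect_error(write_intensity_table(list(), path), "no traces")
  expect_false(file.exists(path))

  tr1 <- intensity_trace(c(0, 1, 2), 1:3)
  tr3 <- intensity_trace(c(0, 2, 4), 1:3)
  expect_error(write_intensity_table(list(tr1, tr3), path), "mismatched")
})

test_that("QC overlay writes a frame-sized PNG with the ROI drawn in place", {
  ph <- generate_phantom(test_phantom_spec(frame_count = 2, noise_sd = 0))
  frame1 <- get_frame(ph$stack, 1)
  well <- build_well_mask(frame1, test_params())
  blobs <- segment_embryos(frame1, well, test_params())
  dets <- lapply(blobs, function(b) {
    fer <- compute_feret(b)
    yolk <- find_yolk_circle(b)
    list(blob = b, feret = fer, yolk = yolk,
         roi = place_roi(b, fer, yolk))
  })
  path <- withr::local_tempfile(fileext = ".png")
  render_qc_overlay(ph$stack, dets, path)
  img <- png::readPNG(path)
  expect_identical(dim(img)[1:2], dim(frame1))

  # each drawn ROI corner carries the overlay colour within 1 px
  for (det in dets) {
    for (i in 1:4) {
      corner <- round(det$roi$corners[i, ])
      patch <- img[max(1, corner[1] - 1):min(dim(img)[1], corner[1] + 1),
                   max(1, corner[2] - 1):min(dim(img)[2], corner[2] + 1), ,
                   drop = FALSE]
      is_red <- patch[, , 1] > 0.9 & patch[, , 2] < 0.5
      expect_true(any(is_red))
    }
  }
})

test_that("QC overlay with no detections writes the plain frame", {
  arr <- array(runif(20 * 20 * 2), dim = c(20, 20, 2))
  fs <- frame_stack(arr, frame_rate = 2)
  path <- withr::local_tempfile(fileext = ".png")
  expect_warning(render_qc_overlay(fs, list(), path), "no detections")
  img <- png::readPNG(path)
  expect_identical(dim(img)[1:2], c(20L, 20L))
})

test_that("trace plots are written for constant, phantom and sine traces", {
  traces <- list(
    intensity_trace(0:9 / 10, rep(5, 10)),
    generate_trace(2.5, noise_sd = 1, seed = 3),
    intensity_trace(0:99 / 10, sin(0:99 / 5) + 2))
  for (tr in traces) {
    path <- withr::local_tempfile(fileext = ".png")
    render_trace_plot(tr, path)
    expect_true(file.exists(path))
    expect_gt(file.size(path), 0)
  }
})
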