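test_that("Feret diameter of simple shapes is exact", {
  line <- matrix(FALSE, 5, 14)
  line[3, 3:12] <- TRUE
  fer <- compute_feret(line)
  expect_equal(fer$length, 9)
  expect_equal(fer$p_start, c(3, 3))
  expect_equal(fer$p_end, c(3, 12))

  disc <- make_disc_mask(64, c(32, 32), 20)
  expect_lt(abs(compute_feret(disc)$length - 40), 1)

  single <- matrix(FALSE, 5, 5)
  single[3, 3] <- TRUE
  expect_error(compute_feret(single), "degenerate")
})

test_that("Feret length equals the all-pairs brute-force maximum", {
  for (s in 1:15) {
    m <- random_blob_mask(s)
    expect_equal(compute_feret(m)$length, brute_feret_length(m),
                 tolerance = 1e-12, label = sprintf("mask seed %d", s))
  }
})

test_that("the inscribed circle of a disc is the disc itself", {
  disc <- make_disc_mask(100, c(50, 50), 25)
  yc <- find_yolk_circle(disc)
  expect_lt(max(abs(yc$center - c(50, 50))), 1 + 1e-9)
  expect_lt(abs(yc$radius - 25), 1 + 1e-9)
})

test_that("inscribed-circle radius matches brute force within 0.5 px", {
  for (s in 1:15) {
    m <- random_blob_mask(s)
    yc <- find_yolk_circle(m)
    expect_lt(abs(yc$radius - brute_inscribed_radius(m)), 0.5)
  }
})

test_that("the inscribed disc is contained in the blob mask", {
  for (s in 1:10) {
    m <- random_blob_mask(s)
    yc <- find_yolk_circle(m)
    inside <- make_disc_mask(nrow(m), yc$center, yc$radius - 1)
    expect_true(all(m[inside]))
  }
})

test_that("thin blobs raise a degenerate-circle error", {
  thin <- matrix(FALSE, 20, 20)
  thin[5:15, 10] <- TRUE
  expect_error(find_yolk_circle(thin), "degenerate circle")
})

test_that("phantom embryo yolk is recovered within 10% of its radius", {
  ph <- generate_phantom(test_phantom_spec(frame_count = 2, noise_sd = 0))
  frame1 <- get_frame(ph$stack, 1)
  well <- build_well_mask(frame1, test_params())
  blobs <- segment_embryos(frame1, well, test_params())
  expect_length(blobs, 2L)
  for (b in blobs) {
    yc <- find_yolk_circle(b)
    expect_lt(abs(yc$radius - 16) / 16, 0.10)
  }
})

make_feret <- function(p, q) {
  structure(list(p_start = p, p_end = q,
                 length = sqrt(sum((q - p)^2))),
            class = "feret_diameter")
}
make_yolk <- function(center, radius) {
  structure(list(center = center, radius = radius), class = "yolk_circle")
}

test_that("ROI construction matches the axis-aligned textbook case", {
  fer <- make_feret(c(0, -40), c(0, 30))
  yolk <- make_yolk(c(0, 0), 10)
  roi <- place_roi(NULL, fer, yolk, scale_w = 1, scale_h = 1 / 3)
  expect_equal(roi$center, c(0, 10))
  expect_equal(roi$width, 10)
  expect_equal(roi$height, 10 / 3)
  # inner edge through (0, 10), perpendicular to the centre->head ray
  inner <- roi$corners[1:2, ]
  expect_equal(sort(inner[, 1]), c(-5, 5))
  expect_equal(unique(inner[, 2]), 10)
  outer_edge <- roi$corners[3:4, ]
  expect_equal(unique(outer_edge[, 2]), 10 + 10 / 3)

  roi2 <- place_roi(NULL, fer, yolk, scale_w = 2, scale_h = 1)
  expect_equal(roi2$width, 20)
  expect_equal(roi2$height, 10)
})

test_that("ROI placement rejects degenerate geometry", {
  yolk <- make_yolk(c(0, 0), 10)
  expect_error(place_roi(NULL, make_feret(c(0, -30), c(0, 30)), yolk),
               "ambiguous")
  expect_error(place_roi(NULL, make_feret(c(0, -40), c(0, 5)), yolk),
               "geometry failure")
})

test_that("ROI placement is equivariant under rotation and translation", {
  base_fer <- c(10, 5, 10, 75)          # p_start, p_end (row, col)
  base_yolk <- c(10, 45)
  for (k in 1:12) {
    angle <- c(37 * pi / 180, seq(0.1, 6.2, length.out = 11))[k]
    shift <- c(3 * k, -2 * k)
    about <- c(20, 20)
    fer0 <- make_feret(base_fer[1:2], base_fer[3:4])
    yolk0 <- make_yolk(base_yolk, 12)
    roi0 <- place_roi(NULL, fer0, yolk0)

    p1 <- rotate_pts(base_fer[1:2], angle, about) + rbind(shift)
    p2 <- rotate_pts(base_fer[3:4], angle, about) + rbind(shift)
    yc <- rotate_pts(base_yolk, angle, about) + rbind(shift)
    roi1 <- place_roi(NULL, make_feret(as.numeric(p1), as.numeric(p2)),
                      make_yolk(as.numeric(yc), 12))

    expected <- rotate_pts(roi0$corners, angle, about) +
      matrix(shift, 4, 2, byrow = TRUE)
    expect_lt(max(abs(roi1$corners - expected)), 0.5)
    expect_equal(roi1$width, roi0$width, tolerance = 1e-9)
    expect_equal(roi1$height, roi0$height, tolerance = 1e-9)
  }
})

test_that("ROI area equals scale_w * scale_h * radius^2 before rasterizing", {
  for (r in c(5, 12, 30)) {
    roi <- place_roi(NULL, make_feret(c(0, -4 * r), c(0, 3 * r)),
                     make_yolk(c(0, 0), r), scale_w = 1.5, scale_h = 0.5)
    expect_equal(roi$width * roi$height, 1.5 * 0.5 * r^2, tolerance = 1e-12)
  }
})

test_that("rasterized ROI pixels all lie inside the rectangle", {
  roi <- place_roi(NULL, make_feret(c(40, 5), c(48, 75)),
                   make_yolk(c(46, 50), 12))
  pix <- roi_pixels(roi, c(100, 100))
  expect_gt(nrow(pix), 0)
  dr <- pix[, 1] - roi$center[1]
  dc <- pix[, 2] - roi$center[2]
  u <- dr * roi$tangent[1] + dc * roi$tangent[2]
  v <- dr * roi$outward[1] + dc * roi$outward[2]
  expect_true(all(abs(u) <= roi$width / 2 + 1e-9))
  expect_true(all(v >= -1e-9 & v <= roi$height + 1e-9))
})
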