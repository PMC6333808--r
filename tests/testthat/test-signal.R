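test_that("ROI extraction averages exactly the fixed pixel set", {
  arr <- array(7, dim = c(40, 40, 6))
  fs <- frame_stack(arr, frame_rate = 3)
  roi <- place_roi(NULL,
                   structure(list(p_start = c(20, 2), p_end = c(20, 34),
                                  length = 32), class = "feret_diameter"),
                   structure(list(center = c(20, 20), radius = 6),
                             class = "yolk_circle"))
  tr <- extract_intensity(fs, roi, embryo_id = 1)
  expect_equal(tr$values, rep(7, 6))
  expect_equal(tr$times, (0:5) / 3)

  # alternate whole frames between 10 and 20
  arr2 <- array(rep(c(10, 20), each = 40 * 40, times = 3),
                dim = c(40, 40, 6))
  tr2 <- extract_intensity(frame_stack(arr2, frame_rate = 3), roi)
  expect_equal(tr2$values, rep(c(10, 20), 3))

  far <- place_roi(NULL,
                   structure(list(p_start = c(500, 2), p_end = c(500, 34),
                                  length = 32), class = "feret_diameter"),
                   structure(list(center = c(500, 20), radius = 6),
                             class = "yolk_circle"))
  expect_error(extract_intensity(fs, far), "empty ROI")
})

test_that("phantom heart oscillation appears in the extracted trace", {
  spec <- test_phantom_spec(noise_sd = 0)
  ph <- generate_phantom(spec)
  cfg <- test_config()
  wr <- process_video(ph$stack, cfg)
  expect_length(wr$traces, 2L)
  for (tr in wr$traces) {
    ptp <- diff(range(tr$values))
    expect_gt(ptp, 0)            # oscillation reaches the ROI mean
  }
})

test_that("drift correction leaves a constant trace untouched", {
  tr <- intensity_trace(0:99 / 10, rep(4.2, 100))
  out <- correct_baseline_drift(tr, 10)
  expect_equal(out$values, tr$values)
  expect_equal(out$segment_offsets, rep(0, 10))
})

test_that("drift correction removes an exact staircase from a sinusoid", {
  # one full period per segment, so segment means are unaffected by the
  # sinusoid and the staircase is recovered exactly
  n <- 160; s <- 10
  t <- 0:(n - 1)
  sine <- sin(2 * pi * t / 16)
  stair <- rep(c(0, 3, -2, 7, 1, -4, 2, 5, -1, 6), each = 16)
  tr <- intensity_trace(t, 50 + sine + stair)
  out <- correct_baseline_drift(tr, s)
  expect_equal(out$values, 50 + sine, tolerance = 1e-9)
  expect_equal(out$segment_offsets, stair[seq(1, n, by = 16)],
               tolerance = 1e-9)
})

test_that("post-correction segment means all equal segment 1's mean", {
  for (s in 1:10) {
    set.seed(s)
    n <- sample(40:200, 1)
    tr <- intensity_trace(seq_len(n), runif(n, 0, 100))
    out <- correct_baseline_drift(tr, 10)
    brk <- floor((0:10) * n / 10)
    means <- vapply(1:10, function(i) {
      mean(out$values[(brk[i] + 1):brk[i + 1]])
    }, numeric(1))
    expect_lt(max(abs(means - means[1])), 1e-9 * max(1, abs(means[1])))
  }
})

test_that("drift correction rejects too-short traces", {
  expect_error(correct_baseline_drift(intensity_trace(1:15, 1:15), 10),
               "insufficient data")
})

test_that("a bin-aligned sinusoid yields its exact rate in bpm", {
  tr <- generate_trace(2.5, frame_count = 165, frame_rate = 16.5)
  res <- estimate_heart_rate(tr)
  expect_true(res$valid)
  expect_equal(res$bpm, 150)
  expect_equal(res$frequency, 2.5)
  # spectrum axis spans 0 up to the Nyquist frequency (odd length: the
  # last bin sits one bin width below it)
  expect_equal(min(res$spectrum_freqs), 0)
  expect_lte(max(res$spectrum_freqs), 16.5 / 2)
  expect_gt(max(res$spectrum_freqs), 16.5 / 2 - 16.5 / 165)
  expect_equal(res$lower_bound, 50)
  expect_equal(res$upper_bound, 200)

  # magnitude scaling by the time step cannot move the argmax
  big <- intensity_trace(tr$times, tr$values * 1000)
  expect_equal(estimate_heart_rate(big)$bpm, 150)
})

test_that("off-bin frequencies land within one DFT bin of the truth", {
  tr <- generate_trace(2.53, frame_count = 165, frame_rate = 16.5)
  res <- estimate_heart_rate(tr)
  bin_bpm <- 60 * 16.5 / 165
  expect_lte(abs(res$bpm - 151.8), bin_bpm)
})

test_that("degenerate spectra are flagged, never silently numeric", {
  const <- estimate_heart_rate(rep(3, 50), frame_rate = 16.5)
  expect_false(const$valid)
  expect_true("zero-signal" %in% const$flags)

  # band above Nyquist for this slow sampling -> no usable bins
  tr <- generate_trace(0.2, frame_count = 64, frame_rate = 1)
  none <- estimate_heart_rate(tr, lower_bpm = 120, upper_bpm = 200)
  expect_false(none$valid)
  expect_true("bounds" %in% none$flags)
})

test_that("rate estimation is invariant under affine intensity maps", {
  set.seed(8)
  for (i in 1:8) {
    tr <- generate_trace(runif(1, 1, 3.3), noise_sd = 2, seed = i)
    r0 <- estimate_heart_rate(tr)
    a <- runif(1, 0.1, 50); b <- runif(1, -100, 100)
    r1 <- estimate_heart_rate(intensity_trace(tr$times, a * tr$values + b))
    expect_equal(r1$bpm, r0$bpm)
  }
})

test_that("the demeaned DC bin can never dominate", {
  set.seed(4)
  for (i in 1:5) {
    tr <- generate_trace(runif(1, 1, 3), noise_sd = 5, seed = 20 + i,
                         baseline = 1e4)
    res <- estimate_heart_rate(tr, lower_bpm = 1e-6, upper_bpm = 1e5)
    expect_gt(res$frequency, 0)
    expect_lt(res$spectrum_mag[1], 1e-6)
  }
})

test_that("well averaging uses valid results only", {
  mk <- function(bpm, valid) {
    structure(list(embryo_id = 1L, well_id = "w", frequency = bpm / 60,
                   bpm = bpm, spectrum_freqs = numeric(0),
                   spectrum_mag = numeric(0), lower_bound = 50,
                   upper_bound = 200, valid = valid, flags = character()),
              class = "heart_rate_result")
  }
  expect_equal(well_average(list(mk(150, TRUE), mk(160, TRUE))), 155)
  expect_equal(well_average(list(mk(150, TRUE), mk(0, FALSE))), 150)
  expect_equal(well_average(list(mk(142, TRUE))), 142)
  expect_error(well_average(list(mk(0, FALSE))), "no valid")
})
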