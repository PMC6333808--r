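#' Extract the ROI mean-intensity trace from a video
#'
#' Applies a fixed ROI (placed once, on the segmentation frame) to every
#' frame of the stack and records the arithmetic mean of the pixel
#' intensities inside it. The heart is more opaque than the static
#' background, so contraction raises and relaxation lowers this mean, and
#' the resulting series oscillates at the heart rate.
#'
#' @param stack A [frame_stack()].
#' @param roi A [place_roi()] result.
#' @param embryo_id Integer label for the trace (defaults to the ROI's).
#' @param well_id Well identifier string.
#' @return An [intensity_trace()] with `times = (frame - 1) / frame_rate`.
#' @export
extract_intensity <- function(stack, roi, embryo_id = roi$embryo_id,
                              well_id = "well") {
  stopifnot(inherits(stack, "frame_stack"), inherits(roi, "heart_roi"))
  d <- dim(stack$frames)
  pix <- roi_pixels(roi, d[1:2])
  if (nrow(pix) == 0L) {
    stop("empty ROI: rectangle rasterizes to no pixels inside the frame",
         call. = FALSE)
  }
  flat <- matrix(stack$frames, nrow = d[1] * d[2])
  lin <- (pix[, "col"] - 1L) * d[1] + pix[, "row"]
  values <- colMeans(flat[lin, , drop = FALSE])
  times <- (seq_len(d[3]) - 1) / stack$frame_rate
  if (is.na(embryo_id)) embryo_id <- 1L
  intensity_trace(times, values, embryo_id = embryo_id, well_id = well_id)
}

segment_bounds <- function(n, s) {
  # segment i (1..s) covers indices (floor((i-1)*n/s)+1) : floor(i*n/s)
  brk <- floor((0:s) * n / s)
  cbind(from = brk[-(s + 1)] + 1L, to = brk[-1])
}

#' Segment-wise baseline drift correction
#'
#' Illumination and focus drift during a recording shifts the ROI baseline
#' slowly relative to the heartbeat. The trace is divided into
#' `segment_count` contiguous, near-equal segments; for every segment after
#' the first, the difference between that segment's mean and the first
#' segment's mean is subtracted from all of its values. Segment 1 is left
#' unchanged. After correction every segment has the same mean as segment 1,
#' which removes staircase and (approximately) slow monotone drift while
#' leaving the beat oscillation intact.
#'
#' @param trace An [intensity_trace()] or a plain numeric vector.
#' @param segment_count Number of segments (default 10, about 1 s of data
#'   per segment for a 10 s recording).
#' @return An object of class `c("drift_corrected_trace",
#'   "intensity_trace")` with corrected `values`, `segment_count`, and
#'   `segment_offsets` (the per-segment subtracted differences; first
#'   element 0).
#' @export
correct_baseline_drift <- function(trace, segment_count = 10L) {
  is_trace <- inherits(trace, "intensity_trace")
  values <- if (is_trace) trace$values else as.numeric(trace)
  n <- length(values)
  s <- as.integer(segment_count)
  stopifnot(s >= 1L)
  if (n < 2L * s) {
    stop(sprintf(
      "insufficient data: %d samples cannot form %d segments of >= 2", n, s),
      call. = FALSE)
  }
  b <- segment_bounds(n, s)
  seg_means <- vapply(seq_len(s),
                      function(i) mean(values[b[i, 1]:b[i, 2]]), numeric(1))
  offsets <- seg_means - seg_means[1]
  corrected <- values
  for (i in seq_len(s)[-1]) {
    corrected[b[i, 1]:b[i, 2]] <- corrected[b[i, 1]:b[i, 2]] - offsets[i]
  }
  out <- if (is_trace) {
    intensity_trace(trace$times, corrected, trace$embryo_id, trace$well_id)
  } else {
    intensity_trace(seq_len(n) - 1, corrected)
  }
  out$segment_count <- s
  out$segment_offsets <- offsets
  class(out) <- c("drift_corrected_trace", class(out))
  out
}

#' Heart rate by dominant-frequency estimation
#'
#' Converts an intensity trace to beats per minute: the series is demeaned,
#' its discrete Fourier transform is computed and its magnitude scaled by
#' the sampling interval, and the one-sided spectrum (0 to the Nyquist
#' frequency, `frame_rate / 2`) is searched for its largest magnitude among
#' bins whose frequency corresponds to a biologically plausible heart rate
#' (`lower_bpm` to `upper_bpm`; defaults 50-200 bpm for embryonic
#' zebrafish). The dominant bin's frequency times 60 is the heart rate. No
#' windowing or peak interpolation is applied, so the estimate is quantized
#' to the bin width `60 * frame_rate / n` bpm (6 bpm for 165 samples at
#' 16.5 frames/s).
#'
#' @param trace An [intensity_trace()] (drift-corrected or raw) or a plain
#'   numeric vector (then `frame_rate` is required).
#' @param frame_rate Sampling rate in frames/s; taken from the trace's time
#'   axis when omitted.
#' @param lower_bpm,upper_bpm Plausible heart-rate bounds in beats/minute.
#' @param embryo_id,well_id Identifiers for the result (default from the
#'   trace).
#' @return An object of class `heart_rate_result`: `frequency` (Hz), `bpm`,
#'   `spectrum_freqs`/`spectrum_mag` (one-sided, magnitude scaled by the
#'   time step), `lower_bound`/`upper_bound` (bpm), `valid`, and `flags`
#'   (`"zero-signal"` for a constant series, `"bounds"` when no spectral
#'   bin falls inside the plausible band).
#' @export
estimate_heart_rate <- function(trace, frame_rate = NULL, lower_bpm = 50,
                                upper_bpm = 200, embryo_id = NULL,
                                well_id = NULL) {
  if (inherits(trace, "intensity_trace")) {
    x <- trace$values
    if (is.null(frame_rate)) frame_rate <- trace_frame_rate(trace)
    if (is.null(embryo_id)) embryo_id <- trace$embryo_id
    if (is.null(well_id)) well_id <- trace$well_id
  } else {
    x <- as.numeric(trace)
    if (is.null(frame_rate)) {
      stop("`frame_rate` is required for a bare numeric trace", call. = FALSE)
    }
  }
  if (is.null(embryo_id)) embryo_id <- NA_integer_
  if (is.null(well_id)) well_id <- NA_character_
  n <- length(x)
  stopifnot(n >= 4L, lower_bpm > 0, lower_bpm < upper_bpm, frame_rate > 0)
  dt <- 1 / frame_rate
  mag <- Mod(stats::fft(x - mean(x))) * dt
  half <- seq_len(floor(n / 2) + 1L)        # one-sided: 0 .. Nyquist
  freqs <- (half - 1) * frame_rate / n
  mag <- mag[half]
  flags <- character()
  valid <- TRUE
  band <- which(freqs * 60 >= lower_bpm & freqs * 60 <= upper_bpm)
  if (diff(range(x)) == 0) {
    valid <- FALSE
    flags <- c(flags, "zero-signal")
  }
  if (length(band) == 0L) {
    valid <- FALSE
    flags <- c(flags, "bounds")
  }
  if (valid) {
    k <- band[which.max(mag[band])]          # ties -> lowest frequency
    frequency <- freqs[k]
  } else {
    frequency <- NA_real_
  }
  structure(list(embryo_id = as.integer(embryo_id),
                 well_id = as.character(well_id),
                 frequency = frequency, bpm = 60 * frequency,
                 spectrum_freqs = freqs, spectrum_mag = mag,
                 lower_bound = lower_bpm, upper_bound = upper_bpm,
                 valid = valid, flags = flags),
            class = "heart_rate_result")
}

#' @export
print.heart_rate_result <- function(x, ...) {
  if (x$valid) {
    cat(sprintf("<heart_rate_result> embryo %s: %.1f bpm (%.3f Hz)\n",
                x$embryo_id, x$bpm, x$frequency))
  } else {
    cat(sprintf("<heart_rate_result> embryo %s: invalid [%s]\n",
                x$embryo_id, paste(x$flags, collapse = ", ")))
  }
  invisible(x)
}

#' @rdname tidy-fishbeat
#' @method tidy heart_rate_result
#' @export
tidy.heart_rate_result <- function(x, ...) {
  tibble::tibble(well_id = x$well_id, embryo_id = x$embryo_id,
                 bpm = x$bpm, dominant_freq_hz = x$frequency,
                 valid = x$valid,
                 flags = paste(x$flags, collapse = ";"))
}

#' Well-averaged heart rate
#'
#' The per-well summary statistic of the assay: the arithmetic mean of the
#' heart rates of all validly captured embryos in the well.
#'
#' @param results A list of [estimate_heart_rate()] results.
#' @return Mean bpm over results with `valid = TRUE`.
#' @export
well_average <- function(results) {
  if (inherits(results, "heart_rate_result")) results <- list(results)
  stopifnot(all(vapply(results, inherits, logical(1), "heart_rate_result")))
  bpm <- vapply(results, function(r) if (r$valid) r$bpm else NA_real_,
                numeric(1))
  bpm <- bpm[!is.na(bpm)]
  if (length(bpm) == 0L) {
    stop("no valid heart-rate results to average", call. = FALSE)
  }
  mean(bpm)
}
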