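#' Synthetic well phantoms with known ground truth
#'
#' A phantom is a rendered bright-field well video whose every property —
#' embryo placement, yolk geometry, true beat frequency, drift, noise — is
#' known, so each pipeline stage can be tested without microscope data. The
#' scene mimics the real assay: a bright circular well interior on a dark
#' plate, dark elliptical embryo bodies with a darker circular yolk sac
#' rostral of the body midpoint, and a small heart disc just rostral of the
#' yolk whose opacity oscillates sinusoidally at the true heart rate.
#'
#' @param center Body-ellipse centre `(row, col)` in pixels.
#' @param a,b Semi-major and semi-minor axes of the body ellipse (pixels,
#'   `a > b`).
#' @param theta Body-axis orientation in radians (direction of the head).
#' @param yolk_offset Yolk-centre position along the axis toward the head,
#'   as a fraction of `a` (must be > 0 so the yolk is rostral of the
#'   midpoint and the shorter Feret segment is the head side).
#' @param yolk_radius Yolk disc radius in pixels; chosen larger than `b` so
#'   the yolk is the fattest round region of the silhouette.
#' @param heart_radius Heart disc radius (pixels).
#' @param heart_offset Heart-centre distance beyond the yolk tangency point
#'   toward the head, as a fraction of `yolk_radius`.
#' @param f_true True beat frequency in Hz (ground-truth rate is
#'   `60 * f_true` bpm).
#' @param heart_baseline,heart_amplitude Heart-disc intensity
#'   `baseline + amplitude * sin(2 pi f_true t)` on the phantom's 0-255
#'   scale.
#' @param body_intensity,yolk_intensity Rendered intensities of body and
#'   yolk.
#' @return A list of class `phantom_embryo`.
#' @export
phantom_embryo <- function(center, a = 80, b = 28, theta = 0,
                           yolk_offset = 0.4, yolk_radius = 32,
                           heart_radius = 9, heart_offset = 0.3,
                           f_true = 2.5, heart_baseline = 95,
                           heart_amplitude = 25, body_intensity = 60,
                           yolk_intensity = 40) {
  stopifnot(a > b, b > 0, yolk_offset > 0, yolk_radius > 0, f_true > 0)
  axis <- c(sin(theta), cos(theta))          # head direction, (row, col)
  yolk_center <- center + yolk_offset * a * axis
  tangency <- yolk_center + yolk_radius * axis
  heart_center <- tangency + heart_offset * yolk_radius * axis
  structure(list(center = center, a = a, b = b, theta = theta, axis = axis,
                 yolk_center = yolk_center, yolk_radius = yolk_radius,
                 heart_center = heart_center, heart_radius = heart_radius,
                 f_true = f_true, heart_baseline = heart_baseline,
                 heart_amplitude = heart_amplitude,
                 body_intensity = body_intensity,
                 yolk_intensity = yolk_intensity,
                 tangency = tangency),
            class = "phantom_embryo")
}

#' Phantom well specification
#'
#' @param image_size `(rows, cols)` of each frame.
#' @param frame_count Number of frames (default 165, a 10 s capture).
#' @param frame_rate Frames per second (default 16.5).
#' @param well_radius Radius of the bright well interior (pixels).
#' @param embryos List of [phantom_embryo()] objects (all bodies must lie
#'   inside the well disc).
#' @param dust List of `list(center = c(row, col), radius = r)` dark
#'   specks emulating lint and dust.
#' @param drift Baseline drift applied to whole frames: `NULL` (none), a
#'   numeric vector of per-frame offsets (length `frame_count`), or a
#'   function of time in seconds returning an offset.
#' @param noise_sd Gaussian sensor-noise standard deviation (intensity
#'   units on the 0-255 scale; default 2).
#' @param seed Integer seed making the rendering deterministic.
#' @param well_intensity,background_intensity Rendered intensities of the
#'   well interior and the surrounding plate.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(image_size = c(512, 512), frame_count = 165,
                         frame_rate = 16.5, well_radius = 240,
                         embryos = list(), dust = list(), drift = NULL,
                         noise_sd = 2, seed = 1, well_intensity = 200,
                         background_intensity = 20) {
  stopifnot(frame_count >= 2, frame_rate > 0, well_radius > 0, noise_sd >= 0)
  ctr <- (image_size + 1) / 2
  for (e in embryos) {
    stopifnot(inherits(e, "phantom_embryo"))
    reach <- sqrt(sum((e$center - ctr)^2)) +
      max(e$a, e$yolk_offset * e$a + e$yolk_radius)
    if (reach > well_radius) {
      stop("phantom spec error: embryo extends outside the well disc",
           call. = FALSE)
    }
  }
  structure(list(image_size = image_size, frame_count = frame_count,
                 frame_rate = frame_rate, well_radius = well_radius,
                 embryos = embryos, dust = dust, drift = drift,
                 noise_sd = noise_sd, seed = seed,
                 well_intensity = well_intensity,
                 background_intensity = background_intensity),
            class = "phantom_spec")
}

# evaluate the drift specification at the frame times
drift_offsets <- function(drift, times) {
  if (is.null(drift)) return(numeric(length(times)))
  if (is.function(drift)) return(vapply(times, drift, numeric(1)))
  if (is.numeric(drift) && length(drift) == length(times)) return(drift)
  stop("`drift` must be NULL, a function of time, or a per-frame vector",
       call. = FALSE)
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(code)
}

ellipse_idx <- function(dims, center, a, b, axis) {
  rlo <- max(1, floor(center[1] - a)); rhi <- min(dims[1], ceiling(center[1] + a))
  clo <- max(1, floor(center[2] - a)); chi <- min(dims[2], ceiling(center[2] + a))
  if (rlo > rhi || clo > chi) return(integer(0))
  g <- expand.grid(row = rlo:rhi, col = clo:chi)
  dr <- g$row - center[1]
  dc <- g$col - center[2]
  u <- dr * axis[1] + dc * axis[2]
  v <- -dr * axis[2] + dc * axis[1]
  g <- g[(u / a)^2 + (v / b)^2 <= 1, , drop = FALSE]
  (g$col - 1L) * dims[1] + g$row
}

disc_idx <- function(dims, center, radius) {
  ellipse_idx(dims, center, radius, radius * (1 - 1e-12), c(1, 0))
}

#' Render a phantom well video
#'
#' Renders the static scene (well, bodies, yolks, dust) once, then per
#' frame sets each heart disc to its oscillating intensity, adds the
#' whole-frame drift offset, and adds i.i.d. Gaussian sensor noise. The
#' result is deterministic for a given `seed`.
#'
#' @param spec A [phantom_spec()].
#' @return A list with `stack` (a [frame_stack()]) and `truth`, a tibble of
#'   per-embryo ground truth: `embryo` (index in spec order), `f_true`
#'   (Hz), `bpm_true`, and the intended ROI target point
#'   (`target_row`, `target_col`, the yolk-circle tangency toward the
#'   head).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  dims <- spec$image_size
  npx <- prod(dims)
  ctr <- (dims + 1) / 2
  base <- rep(spec$background_intensity, npx)
  base[disc_idx(dims, ctr, spec$well_radius)] <- spec$well_intensity
  hearts <- vector("list", length(spec$embryos))
  for (i in seq_along(spec$embryos)) {
    e <- spec$embryos[[i]]
    base[ellipse_idx(dims, e$center, e$a, e$b, e$axis)] <- e$body_intensity
    base[disc_idx(dims, e$yolk_center, e$yolk_radius)] <- e$yolk_intensity
    hearts[[i]] <- disc_idx(dims, e$heart_center, e$heart_radius)
  }
  for (d in spec$dust) {
    base[disc_idx(dims, d$center, d$radius)] <- 50
  }
  times <- (seq_len(spec$frame_count) - 1) / spec$frame_rate
  off <- drift_offsets(spec$drift, times)
  frames <- with_seed(spec$seed, {
    arr <- array(0, dim = c(dims, spec$frame_count))
    for (t in seq_len(spec$frame_count)) {
      f <- base
      for (i in seq_along(spec$embryos)) {
        e <- spec$embryos[[i]]
        f[hearts[[i]]] <- e$heart_baseline +
          e$heart_amplitude * sin(2 * pi * e$f_true * times[t])
      }
      f <- f + off[t]
      if (spec$noise_sd > 0) f <- f + stats::rnorm(npx, 0, spec$noise_sd)
      arr[, , t] <- pmax(f, 0)
    }
    arr
  })
  truth <- tibble::tibble(
    embryo = seq_along(spec$embryos),
    f_true = vapply(spec$embryos, `[[`, numeric(1), "f_true"),
    bpm_true = 60 * vapply(spec$embryos, `[[`, numeric(1), "f_true"),
    target_row = vapply(spec$embryos, function(e) e$tangency[1], numeric(1)),
    target_col = vapply(spec$embryos, function(e) e$tangency[2], numeric(1)))
  list(stack = frame_stack(frames, frame_rate = spec$frame_rate,
                           source_path = sprintf("<phantom seed %d>",
                                                 spec$seed)),
       truth = truth)
}

#' Generate a synthetic intensity trace
#'
#' Unit-level fixture for the signal stage: a sinusoid at the true beat
#' frequency plus baseline, optional drift, and Gaussian noise.
#'
#' @param f_true Beat frequency in Hz; must be below the Nyquist frequency
#'   `frame_rate / 2`.
#' @param frame_count,frame_rate Sampling grid (defaults 165 at 16.5).
#' @param amplitude,baseline Sinusoid amplitude and mean level.
#' @param drift As in [phantom_spec()].
#' @param noise_sd Gaussian noise standard deviation.
#' @param seed Seed for the noise.
#' @param embryo_id,well_id Trace identifiers.
#' @return An [intensity_trace()].
#' @export
generate_trace <- function(f_true, frame_count = 165, frame_rate = 16.5,
                           amplitude = 10, baseline = 100, drift = NULL,
                           noise_sd = 0, seed = 1, embryo_id = 1L,
                           well_id = "phantom") {
  if (f_true >= frame_rate / 2) {
    stop("aliasing: `f_true` must be below the Nyquist frequency",
         call. = FALSE)
  }
  times <- (seq_len(frame_count) - 1) / frame_rate
  values <- baseline + amplitude * sin(2 * pi * f_true * times) +
    drift_offsets(drift, times)
  if (noise_sd > 0) {
    values <- values + with_seed(seed, stats::rnorm(frame_count, 0, noise_sd))
  }
  intensity_trace(times, values, embryo_id = embryo_id, well_id = well_id)
}

#' Random phantom well specifications
#'
#' Draws a phantom with embryos at random positions and orientations inside
#' the well and random true beat frequencies, for property-style testing of
#' the full pipeline. Geometry scales with `image_size` relative to the
#' default 512-pixel well.
#'
#' @param n_embryos Number of embryos (default 2, the assay's standard
#'   housing density).
#' @param f_range True-beat-frequency range in Hz (default 1.0-3.3,
#'   spanning 60-198 bpm).
#' @param seed Integer seed; drives both the layout draw and the rendering
#'   noise.
#' @param image_size Frame dimensions (default `c(512, 512)`).
#' @param ... Passed on to [phantom_spec()] (e.g. `noise_sd`, `drift`,
#'   `dust`, `frame_count`).
#' @return A [phantom_spec()].
#' @export
random_phantom_spec <- function(n_embryos = 2, f_range = c(1.0, 3.3),
                                seed = 1, image_size = c(512, 512), ...) {
  sc <- min(image_size) / 512
  well_radius <- 240 * sc
  ctr <- (image_size + 1) / 2
  a <- 80 * sc
  with_seed(seed, {
    # one embryo per angular sector, with jittered angle and radius;
    # retried until no two bodies can touch (overlapping embryos are a
    # separate, deliberately constructed test case)
    centers <- NULL
    for (attempt in 1:200) {
      base <- stats::runif(1, 0, 2 * pi)
      ang <- base + 2 * pi * (seq_len(n_embryos) - 1) / n_embryos +
        stats::runif(n_embryos, -0.3, 0.3)
      rad <- stats::runif(n_embryos, 0.35, 0.6) * well_radius
      cand <- cbind(ctr[1] + rad * sin(ang), ctr[2] + rad * cos(ang))
      if (n_embryos == 1L ||
          min(stats::dist(cand)) >= 2.05 * a) {
        centers <- cand
        break
      }
    }
    if (is.null(centers)) {
      stop("could not place embryos without overlap", call. = FALSE)
    }
    embryos <- lapply(seq_len(n_embryos), function(i) {
      phantom_embryo(
        center = centers[i, ], a = a, b = 28 * sc,
        theta = stats::runif(1, 0, 2 * pi), yolk_radius = 32 * sc,
        heart_radius = 9 * sc,
        f_true = stats::runif(1, f_range[1], f_range[2]))
    })
    phantom_spec(image_size = image_size, well_radius = well_radius,
                 embryos = embryos, seed = seed, ...)
  })
}

#' Detection parameters matched to a phantom's scale
#'
#' Area gates scale with the square of the linear image scale relative to
#' the default 512-pixel phantom well.
#'
#' @param image_size Frame dimensions of the phantom.
#' @param ... Overrides passed to [detection_params()].
#' @return A [detection_params()] list.
#' @export
phantom_detection_params <- function(image_size = c(512, 512), ...) {
  sc2 <- (min(image_size) / 512)^2
  defaults <- list(min_area = 2000 * sc2, max_area = 200000 * sc2,
                   max_single_area = 30000 * sc2)
  args <- utils::modifyList(defaults, list(...))
  do.call(detection_params, args)
}
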