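#' Quality-control renderings
#'
#' After each well is processed, a still image with the detected geometry
#' superimposed is saved so that ROI placement can be audited at a glance,
#' together with per-embryo intensity-versus-time plots.
#'
#' @name qc
NULL

# 3 x 5 bitmap glyphs for digits, scaled up at draw time
.digit_font <- lapply(list(
  c(1,1,1, 1,0,1, 1,0,1, 1,0,1, 1,1,1),
  c(0,1,0, 1,1,0, 0,1,0, 0,1,0, 1,1,1),
  c(1,1,1, 0,0,1, 1,1,1, 1,0,0, 1,1,1),
  c(1,1,1, 0,0,1, 1,1,1, 0,0,1, 1,1,1),
  c(1,0,1, 1,0,1, 1,1,1, 0,0,1, 0,0,1),
  c(1,1,1, 1,0,0, 1,1,1, 0,0,1, 1,1,1),
  c(1,1,1, 1,0,0, 1,1,1, 1,0,1, 1,1,1),
  c(1,1,1, 0,0,1, 0,1,0, 0,1,0, 0,1,0),
  c(1,1,1, 1,0,1, 1,1,1, 1,0,1, 1,1,1),
  c(1,1,1, 1,0,1, 1,1,1, 0,0,1, 1,1,1)),
  function(v) matrix(v, 5, 3, byrow = TRUE))

set_px <- function(img, rows, cols, color) {
  d <- dim(img)
  ok <- rows >= 1 & rows <= d[1] & cols >= 1 & cols <= d[2]
  rows <- rows[ok]; cols <- cols[ok]
  for (ch in 1:3) {
    img[cbind(rows, cols, ch)] <- color[ch]
  }
  img
}

draw_segment <- function(img, p, q, color) {
  n <- max(2L, ceiling(2 * sqrt(sum((q - p)^2))))
  t <- seq(0, 1, length.out = n)
  set_px(img, round(p[1] + t * (q[1] - p[1])),
         round(p[2] + t * (q[2] - p[2])), color)
}

draw_circle_outline <- function(img, center, radius, color) {
  n <- max(16L, ceiling(4 * pi * radius))
  a <- seq(0, 2 * pi, length.out = n)
  set_px(img, round(center[1] + radius * sin(a)),
         round(center[2] + radius * cos(a)), color)
}

draw_text <- function(img, origin, text, color, scale = 3L) {
  chars <- strsplit(text, "")[[1]]
  col0 <- origin[2]
  for (ch in chars) {
    glyph <- .digit_font[[as.integer(ch) + 1L]]
    on <- which(glyph == 1, arr.ind = TRUE)
    for (s1 in seq_len(scale)) for (s2 in seq_len(scale)) {
      img <- set_px(img,
                    origin[1] + (on[, 1] - 1L) * scale + s1 - 1L,
                    col0 + (on[, 2] - 1L) * scale + s2 - 1L, color)
    }
    col0 <- col0 + 4L * scale
  }
  img
}

#' Save a still frame with detection geometry superimposed
#'
#' Writes a PNG of the first frame with, for every detection, the heart
#' ROI rectangle (red), the yolk circle (yellow), the Feret diameter
#' (cyan), and the embryo identifier drawn near its centroid. The output
#' has exactly the height and width of a video frame, so overlay
#' coordinates correspond to image pixels one-to-one.
#'
#' @param stack A [frame_stack()].
#' @param detections A list of detection records, each a list with
#'   `blob` (an `embryo_blob`), `feret`, `yolk`, and `roi` components
#'   (any of which except `blob` may be `NULL` if that stage failed).
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
render_qc_overlay <- function(stack, detections, path) {
  stopifnot(inherits(stack, "frame_stack"))
  f <- get_frame(stack, 1L)
  rng <- range(f)
  g <- if (diff(rng) > 0) (f - rng[1]) / diff(rng) else f * 0
  img <- array(g, dim = c(dim(f), 3L))
  if (length(detections) == 0L) {
    warning("no detections to draw; writing plain first frame",
            call. = FALSE)
  }
  red <- c(1, 0.1, 0.1); yellow <- c(1, 0.9, 0.1); cyan <- c(0.1, 0.9, 1)
  for (det in detections) {
    if (!is.null(det$feret)) {
      img <- draw_segment(img, det$feret$p_start, det$feret$p_end, cyan)
    }
    if (!is.null(det$yolk)) {
      img <- draw_circle_outline(img, det$yolk$center, det$yolk$radius,
                                 yellow)
    }
    if (!is.null(det$roi)) {
      cr <- det$roi$corners
      for (i in 1:4) {
        img <- draw_segment(img, cr[i, ], cr[i %% 4 + 1, ], red)
      }
    }
    if (!is.null(det$blob)) {
      img <- draw_text(img, round(det$blob$centroid) + c(-7L, -4L),
                       as.character(det$blob$label), red)
    }
  }
  png::writePNG(img, path)
  invisible(path)
}

#' @rdname qc
#' @param object,x An [intensity_trace()] or [estimate_heart_rate()] result.
#' @param ... Unused.
#' @method autoplot intensity_trace
#' @export
autoplot.intensity_trace <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$intensity)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::labs(x = "time (s)", y = "mean ROI pixel intensity",
                  title = sprintf("well %s, embryo %d",
                                  object$well_id, object$embryo_id)) +
    ggplot2::theme_minimal()
}

#' @rdname qc
#' @method autoplot heart_rate_result
#' @export
autoplot.heart_rate_result <- function(object, ...) {
  df <- tibble::tibble(freq = object$spectrum_freqs,
                       magnitude = object$spectrum_mag)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$freq,
                                        y = .data$magnitude)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::annotate("rect", xmin = object$lower_bound / 60,
                      xmax = object$upper_bound / 60, ymin = -Inf,
                      ymax = Inf, alpha = 0.08, fill = "steelblue") +
    ggplot2::labs(x = "frequency (Hz)", y = "|X(f)| * dt",
                  title = if (object$valid)
                    sprintf("embryo %d: %.1f bpm", object$embryo_id,
                            object$bpm)
                  else sprintf("embryo %d: invalid", object$embryo_id)) +
    ggplot2::theme_minimal()
  if (object$valid) {
    p <- p + ggplot2::geom_vline(xintercept = object$frequency,
                                 linetype = "dashed", colour = "firebrick")
  }
  p
}

#' @rdname qc
#' @method autoplot bland_altman
#' @export
autoplot.bland_altman <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean, y = .data$difference)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = object$bias, colour = "firebrick") +
    ggplot2::geom_hline(yintercept = c(object$loa_low, object$loa_high),
                        linetype = "dashed") +
    ggplot2::labs(x = "mean of methods (bpm)",
                  y = "difference between methods (bpm)") +
    ggplot2::theme_minimal()
}

#' Save an intensity-versus-time plot
#'
#' @param trace An [intensity_trace()].
#' @param path Output PNG path.
#' @param width,height,dpi Device size passed to [ggplot2::ggsave()].
#' @return `path`, invisibly.
#' @export
render_trace_plot <- function(trace, path, width = 6, height = 3,
                              dpi = 120) {
  stopifnot(inherits(trace, "intensity_trace"))
  ggplot2::ggsave(path, autoplot(trace), width = width, height = height,
                  dpi = dpi)
  invisible(path)
}
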