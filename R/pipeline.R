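#' Pipeline configuration
#'
#' One bag of settings for the full well-to-heart-rate pipeline. Every
#' value has a working default matching the reference acquisition (16.5
#' frames/s for 10 s, 3.24 um/pixel, up to five embryos per well).
#'
#' @param frame_rate Frames per second of the recordings.
#' @param scale_w,scale_h ROI scaling factors (multiples of the yolk
#'   radius); see [place_roi()].
#' @param lower_bpm,upper_bpm Plausible heart-rate band for the spectral
#'   search.
#' @param segment_count Segments for [correct_baseline_drift()].
#' @param max_embryos Maximum embryos processed per well; additional blobs
#'   beyond this count are dropped (largest kept) with a flag.
#' @param detection A [detection_params()] list.
#' @param out_dir Output directory for tables and QC artifacts; `NULL`
#'   disables file output.
#' @param write_trace_plots Also write per-embryo trace plots (slower;
#'   default `FALSE`).
#' @return A list of class `run_config`.
#' @export
run_config <- function(frame_rate = 16.5, scale_w = 1, scale_h = 1 / 3,
                       lower_bpm = 50, upper_bpm = 200, segment_count = 10L,
                       max_embryos = 5L, detection = detection_params(),
                       out_dir = NULL, write_trace_plots = FALSE) {
  stopifnot(frame_rate > 0, scale_w > 0, scale_h > 0,
            lower_bpm > 0, lower_bpm < upper_bpm, segment_count >= 1,
            max_embryos >= 1, inherits(detection, "detection_params"))
  structure(list(frame_rate = frame_rate, scale_w = scale_w,
                 scale_h = scale_h, lower_bpm = lower_bpm,
                 upper_bpm = upper_bpm,
                 segment_count = as.integer(segment_count),
                 max_embryos = as.integer(max_embryos),
                 detection = detection, out_dir = out_dir,
                 write_trace_plots = isTRUE(write_trace_plots)),
            class = "run_config")
}

#' Process one well video end to end
#'
#' Runs the complete chain on a single stack: well masking, embryo
#' segmentation, per-embryo geometry (Feret diameter, yolk circle, heart
#' ROI), ROI intensity extraction, baseline drift correction, spectral
#' heart-rate estimation, and well averaging. An embryo whose geometry or
#' signal stage fails is recorded with its failure flag and skipped; it
#' never aborts the well. When `config$out_dir` is set, the intensity
#' table (TSV), the per-embryo results (CSV) and the QC overlay (PNG) are
#' written there.
#'
#' @param x A [frame_stack()] or a path readable by [load_stack()].
#' @param config A [run_config()].
#' @param well_id Well identifier; defaults to the file name stem (or
#'   `"well"` for in-memory stacks).
#' @return A list of class `well_result`: `well_id`, `results` (list of
#'   `heart_rate_result`), `well_bpm` (`NA` when no embryo was validly
#'   captured), `detections` (blob/feret/yolk/roi records), `traces`,
#'   `flags`, and `artifacts` (paths written).
#' @export
process_video <- function(x, config = run_config(), well_id = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (inherits(x, "frame_stack")) {
    stack <- x
    if (is.null(well_id)) well_id <- "well"
  } else {
    stack <- load_stack(x, frame_rate = config$frame_rate)
    if (is.null(well_id)) {
      well_id <- tools::file_path_sans_ext(basename(x))
    }
  }
  flags <- character()
  frame1 <- get_frame(stack, 1L)
  well <- build_well_mask(frame1, config$detection)
  if (well$fallback) flags <- c(flags, "well-mask-fallback")
  blobs <- segment_embryos(frame1, well, config$detection)
  if (length(blobs) == 0L) {
    warning(sprintf("well %s: no embryos detected", well_id), call. = FALSE)
    flags <- c(flags, "no-embryos")
  }
  if (length(blobs) > config$max_embryos) {
    areas <- vapply(blobs, `[[`, numeric(1), "area")
    blobs <- blobs[order(-areas)[seq_len(config$max_embryos)]]
    blobs <- blobs[order(vapply(blobs, `[[`, numeric(1), "label"))]
    flags <- c(flags, "max-embryos-exceeded")
  }
  detections <- list()
  traces <- list()
  results <- list()
  for (blob in blobs) {
    det <- list(blob = blob, feret = NULL, yolk = NULL, roi = NULL)
    res <- tryCatch({
      det$feret <- compute_feret(blob)
      det$yolk <- find_yolk_circle(blob)
      det$roi <- place_roi(blob, det$feret, det$yolk,
                           scale_w = config$scale_w,
                           scale_h = config$scale_h)
      trace <- extract_intensity(stack, det$roi, embryo_id = blob$label,
                                 well_id = well_id)
      traces[[length(traces) + 1L]] <- trace
      corrected <- correct_baseline_drift(trace, config$segment_count)
      r <- estimate_heart_rate(corrected, lower_bpm = config$lower_bpm,
                               upper_bpm = config$upper_bpm)
      r$flags <- c(blob$flags, r$flags)
      r
    }, error = function(e) {
      warning(sprintf("well %s embryo %d skipped: %s", well_id, blob$label,
                      conditionMessage(e)), call. = FALSE)
      structure(list(embryo_id = blob$label, well_id = well_id,
                     frequency = NA_real_, bpm = NA_real_,
                     spectrum_freqs = numeric(0),
                     spectrum_mag = numeric(0),
                     lower_bound = config$lower_bpm,
                     upper_bound = config$upper_bpm, valid = FALSE,
                     flags = c(blob$flags,
                               paste0("stage-error: ",
                                      conditionMessage(e)))),
                class = "heart_rate_result")
    })
    detections[[length(detections) + 1L]] <- det
    results[[length(results) + 1L]] <- res
  }
  n_valid <- sum(vapply(results, `[[`, logical(1), "valid"))
  well_bpm <- if (n_valid > 0) well_average(results) else NA_real_
  if (length(blobs) > 0L && n_valid == 0L) flags <- c(flags, "uncaptured")
  artifacts <- character()
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    stem <- file.path(config$out_dir, well_id)
    overlay <- paste0(stem, "_overlay.png")
    suppressWarnings(render_qc_overlay(stack, detections, overlay))
    artifacts <- c(artifacts, overlay)
    if (length(traces) > 0L) {
      tsv <- paste0(stem, "_intensity.tsv")
      write_intensity_table(traces, tsv)
      artifacts <- c(artifacts, tsv)
    }
    if (length(results) > 0L) {
      csv <- paste0(stem, "_results.csv")
      utils::write.csv(dplyr::bind_rows(lapply(results, tidy)), csv,
                       row.names = FALSE)
      artifacts <- c(artifacts, csv)
    }
    if (config$write_trace_plots) {
      for (tr in traces) {
        p <- sprintf("%s_embryo%d_trace.png", stem, tr$embryo_id)
        render_trace_plot(tr, p)
        artifacts <- c(artifacts, p)
      }
    }
  }
  structure(list(well_id = well_id, results = results, well_bpm = well_bpm,
                 detections = detections, traces = traces, flags = flags,
                 artifacts = artifacts),
            class = "well_result")
}

#' @export
print.well_result <- function(x, ...) {
  cat(sprintf("<well_result> %s: %d embryo(s), well average %s bpm%s\n",
              x$well_id, length(x$results),
              if (is.na(x$well_bpm)) "NA" else sprintf("%.1f", x$well_bpm),
              if (length(x$flags)) paste0(" [", paste(x$flags,
                                                      collapse = ", "), "]")
              else ""))
  invisible(x)
}

#' @rdname tidy-fishbeat
#' @method tidy well_result
#' @export
tidy.well_result <- function(x, ...) {
  if (length(x$results) == 0L) {
    return(tibble::tibble(well_id = character(0), embryo_id = integer(0),
                          bpm = numeric(0), dominant_freq_hz = numeric(0),
                          valid = logical(0), flags = character(0)))
  }
  dplyr::bind_rows(lapply(x$results, tidy))
}

#' @rdname glance-fishbeat
#' @method glance well_result
#' @export
glance.well_result <- function(x, ...) {
  tibble::tibble(well_id = x$well_id,
                 n_embryos = length(x$results),
                 n_valid = sum(vapply(x$results, `[[`, logical(1), "valid")),
                 well_bpm = x$well_bpm,
                 flags = paste(x$flags, collapse = ";"))
}

#' Process a directory of well videos
#'
#' Runs [process_video()] over every readable stack in a directory
#' (multi-page TIFFs, plus subdirectories of single frames), in
#' deterministic lexicographic filename order. A failure in one well is
#' flagged in its summary row and never aborts the batch. The well
#' identifier is the file name stem.
#'
#' @param dir Directory of stacks.
#' @param config A [run_config()].
#' @return A tibble with one row per well (`well_id`, `n_embryos`,
#'   `n_valid`, `well_bpm`, `flags`), with attributes `capture_rate` (the
#'   fraction of wells yielding at least one valid embryo) and `results`
#'   (the list of `well_result` objects, named by well).
#' @export
process_directory <- function(dir, config = run_config()) {
  if (!dir.exists(dir)) stop(sprintf("no such directory: '%s'", dir),
                             call. = FALSE)
  files <- list.files(dir, pattern = "\\.(tif|tiff)$", ignore.case = TRUE,
                      full.names = TRUE)
  subdirs <- list.dirs(dir, recursive = FALSE)
  inputs <- c(files, subdirs)
  inputs <- inputs[order(basename(inputs), method = "radix")]
  if (length(inputs) == 0L) {
    stop(sprintf("no input stacks found in '%s'", dir), call. = FALSE)
  }
  rows <- vector("list", length(inputs))
  wells <- vector("list", length(inputs))
  for (i in seq_along(inputs)) {
    wid <- tools::file_path_sans_ext(basename(inputs[i]))
    wr <- tryCatch(
      suppressWarnings(process_video(inputs[i], config, well_id = wid)),
      error = function(e) e)
    if (inherits(wr, "error")) {
      rows[[i]] <- tibble::tibble(
        well_id = wid, n_embryos = 0L, n_valid = 0L, well_bpm = NA_real_,
        flags = paste0("read-error: ", conditionMessage(wr)))
    } else {
      rows[[i]] <- glance(wr)
      wells[[i]] <- wr
    }
  }
  out <- dplyr::bind_rows(rows)
  names(wells) <- out$well_id
  attr(out, "capture_rate") <- mean(out$n_valid >= 1)
  attr(out, "results") <- wells[!vapply(wells, is.null, logical(1))]
  out
}
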