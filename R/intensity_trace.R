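#' Per-embryo intensity traces
#'
#' An `intensity_trace` is the mean pixel intensity of one embryo's heart
#' region of interest (ROI), sampled once per video frame. It is the
#' quantity the whole pipeline revolves around: the heart is more opaque
#' than the static background, so each contraction raises the ROI mean and
#' each relaxation lowers it, and the trace oscillates at the heart rate.
#'
#' @param times Sample times in seconds; strictly increasing with uniform
#'   spacing `1/frame_rate`.
#' @param values Mean ROI intensity per frame; same length as `times`.
#' @param embryo_id Positive integer embryo label within the well.
#' @param well_id Well identifier string.
#' @return An object of class `intensity_trace`.
#' @export
intensity_trace <- function(times, values, embryo_id = 1L, well_id = "well") {
  times <- as.numeric(times)
  values <- as.numeric(values)
  if (length(times) != length(values) || length(times) < 2L) {
    stop("`times` and `values` must have equal length >= 2", call. = FALSE)
  }
  dt <- diff(times)
  if (any(dt <= 0)) stop("`times` must be strictly increasing", call. = FALSE)
  if (max(abs(dt - dt[1])) > 1e-9 * max(dt[1], 1e-12)) {
    stop("`times` must be uniformly spaced", call. = FALSE)
  }
  structure(
    list(times = times, values = values,
         embryo_id = as.integer(embryo_id), well_id = as.character(well_id)),
    class = "intensity_trace"
  )
}

#' @export
print.intensity_trace <- function(x, ...) {
  cat(sprintf(
    "<intensity_trace> well %s embryo %d: %d samples over %.3g s (dt = %.4g s)\n",
    x$well_id, x$embryo_id, length(x$times),
    utils::tail(x$times, 1) - x$times[1], x$times[2] - x$times[1]))
  invisible(x)
}

trace_frame_rate <- function(trace) 1 / (trace$times[2] - trace$times[1])

#' @rdname tidy-fishbeat
#' @method tidy intensity_trace
#' @export
tidy.intensity_trace <- function(x, ...) {
  tibble::tibble(well_id = x$well_id, embryo_id = x$embryo_id,
                 time = x$times, intensity = x$values)
}

#' Write intensity traces to a tab-delimited text file
#'
#' Writes the per-embryo mean-ROI-intensity series of one well in the
#' pipeline's text exchange format: a header row, a first column `time_s`,
#' and one column `embryo_<id>` per trace. All traces must share the same
#' time axis. Values are printed with enough digits for a read-back to
#' reproduce them to at least 6 significant digits.
#'
#' @param traces A list of [intensity_trace()] objects (at least one).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_intensity_table <- function(traces, path) {
  if (length(traces) == 0L) {
    stop("no traces to write", call. = FALSE)
  }
  if (inherits(traces, "intensity_trace")) traces <- list(traces)
  stopifnot(all(vapply(traces, inherits, logical(1), "intensity_trace")))
  t0 <- traces[[1]]$times
  for (tr in traces[-1]) {
    if (length(tr$times) != length(t0) || max(abs(tr$times - t0)) > 1e-9) {
      stop("traces have mismatched time axes and cannot be aligned",
           call. = FALSE)
    }
  }
  tab <- data.frame(time_s = t0)
  for (tr in traces) tab[[sprintf("embryo_%d", tr$embryo_id)]] <- tr$values
  utils::write.table(format(tab, digits = 12, scientific = FALSE,
                            trim = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a tab-delimited intensity table back into traces
#'
#' Inverse of [write_intensity_table()].
#'
#' @param path File written by [write_intensity_table()].
#' @param well_id Well identifier to attach to the traces.
#' @return A list of [intensity_trace()] objects, one per embryo column.
#' @export
read_intensity_table <- function(path, well_id = "well") {
  tab <- utils::read.delim(path, check.names = FALSE)
  if (!"time_s" %in% names(tab) || ncol(tab) < 2L) {
    stop(sprintf("'%s' is not an intensity table", path), call. = FALSE)
  }
  cols <- setdiff(names(tab), "time_s")
  lapply(cols, function(cn) {
    intensity_trace(tab$time_s, tab[[cn]],
                    embryo_id = as.integer(sub("^embryo_", "", cn)),
                    well_id = well_id)
  })
}
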