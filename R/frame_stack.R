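#' Frame stacks: the in-memory representation of a well video
#'
#' A `frame_stack` holds an ordered sequence of grayscale frames of one
#' microplate well together with its acquisition metadata. Frames are stored
#' as a numeric array of dimension `rows x cols x n_frames`; pixel
#' coordinates throughout the package are 1-based `(row, col)` with the
#' origin at the top-left corner of the image.
#'
#' @param frames Numeric array, `rows x cols x n_frames` (a single matrix is
#'   accepted and treated as rows x cols x 1 only if `n_frames` would be
#'   >= 2 after stacking, so in practice pass a 3-D array). Intensities must
#'   be finite and non-negative; the absolute scale is arbitrary (8-, 11- or
#'   16-bit camera counts, or floats).
#' @param frame_rate Acquisition rate in frames per second. Must be > 0.
#'   The default, 16.5, matches a 10 s capture yielding about 165 frames.
#' @param pixel_size Micrometers per pixel (metadata only; default 3.24).
#' @param source_path Provenance string, e.g. the file the stack was read
#'   from.
#'
#' @return An object of class `frame_stack`.
#' @export
frame_stack <- function(frames, frame_rate = 16.5, pixel_size = 3.24,
                        source_path = "<memory>") {
  if (is.matrix(frames)) {
    frames <- array(frames, dim = c(dim(frames), 1L))
  }
  if (!is.array(frames) || length(dim(frames)) != 3L) {
    stop("`frames` must be a rows x cols x n_frames array", call. = FALSE)
  }
  storage.mode(frames) <- "double"
  if (dim(frames)[3] < 2L) {
    stop("insufficient data: a frame stack needs at least 2 frames",
         call. = FALSE)
  }
  if (!is.numeric(frame_rate) || length(frame_rate) != 1L || frame_rate <= 0) {
    stop("`frame_rate` must be a single positive number", call. = FALSE)
  }
  if (anyNA(frames) || any(!is.finite(frames)) || any(frames < 0)) {
    stop("frame intensities must be finite and non-negative", call. = FALSE)
  }
  structure(
    list(frames = frames, frame_rate = as.numeric(frame_rate),
         pixel_size = as.numeric(pixel_size),
         source_path = as.character(source_path)),
    class = "frame_stack"
  )
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "<frame_stack> %d frames of %d x %d px, %.3g fps (%.3g s), %.3g um/px\n",
    d[3], d[1], d[2], x$frame_rate, d[3] / x$frame_rate, x$pixel_size))
  cat("  source:", x$source_path, "\n")
  invisible(x)
}

#' @export
dim.frame_stack <- function(x) dim(x$frames)

n_frames <- function(stack) dim(stack$frames)[3]

#' Extract one frame from a stack
#'
#' @param stack A [frame_stack()].
#' @param i Frame index (1-based).
#' @return A numeric matrix (rows x cols).
#' @export
get_frame <- function(stack, i = 1L) {
  stopifnot(inherits(stack, "frame_stack"))
  if (i < 1L || i > n_frames(stack)) stop("frame index out of range")
  stack$frames[, , i]
}

# Collapse a tiff/png frame read as rows x cols x channels to grayscale by
# unweighted channel mean (bright-field channels are near-identical).
collapse_channels <- function(m) {
  if (is.matrix(m)) return(m)
  if (is.array(m) && length(dim(m)) == 3L) {
    return(rowMeans(m, dims = 2L))
  }
  stop("unsupported frame layout")
}

#' Read a well video from disk
#'
#' Reads either a multi-page TIFF or a directory of single-frame images
#' (TIFF or PNG, ordered lexicographically by file name) into a
#' [frame_stack()]. Multi-channel (RGB) frames are collapsed to a single
#' channel by averaging channels. TIFF metadata does not reliably carry the
#' acquisition rate, so `frame_rate` is an explicit argument.
#'
#' @param path Path to a multi-page TIFF file or to a directory of frames.
#' @param frame_rate Frames per second of the recording (default 16.5).
#' @param pixel_size Micrometers per pixel (default 3.24).
#' @return A [frame_stack()] with frames in temporal order. Integer pixel
#'   data read from 8/16-bit files is rescaled by the reader to `[0, 1]`;
#'   the pipeline is invariant to that affine rescaling.
#' @export
load_stack <- function(path, frame_rate = 16.5, pixel_size = 3.24) {
  if (!file.exists(path)) {
    stop(sprintf("cannot read '%s': no such file or directory", path),
         call. = FALSE)
  }
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.(tif|tiff|png)$",
                        ignore.case = TRUE, full.names = TRUE)
    files <- files[order(basename(files), method = "radix")]
    if (length(files) < 2L) {
      stop(sprintf("insufficient data: '%s' holds %d readable frame(s)",
                   path, length(files)), call. = FALSE)
    }
    frames <- lapply(files, read_frame_file)
  } else {
    frames <- tryCatch(
      tiff::readTIFF(path, all = TRUE),
      error = function(e) {
        stop(sprintf("cannot parse '%s' as a TIFF stack: %s",
                     path, conditionMessage(e)), call. = FALSE)
      })
    if (!is.list(frames)) frames <- list(frames)
    if (length(frames) < 2L) {
      stop(sprintf("insufficient data: '%s' holds %d frame(s)",
                   path, length(frames)), call. = FALSE)
    }
  }
  frames <- lapply(frames, collapse_channels)
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop(sprintf("dimension mismatch across frames of '%s'", path),
         call. = FALSE)
  }
  arr <- array(unlist(frames, use.names = FALSE),
               dim = c(dims[1, 1], dims[2, 1], length(frames)))
  frame_stack(arr, frame_rate = frame_rate, pixel_size = pixel_size,
              source_path = normalizePath(path))
}

read_frame_file <- function(f) {
  ext <- tolower(tools::file_ext(f))
  img <- tryCatch(
    if (ext == "png") png::readPNG(f) else tiff::readTIFF(f),
    error = function(e) {
      stop(sprintf("cannot read frame '%s': %s", f, conditionMessage(e)),
           call. = FALSE)
    })
  img
}

#' Write a frame stack to a multi-page TIFF
#'
#' Intensities are written as 16-bit samples; the stack is scaled into
#' `[0, 1]` by its maximum (or `max_value` if supplied) before writing, so a
#' stack generated on a 0-255 float scale round-trips through
#' [load_stack()] up to that affine rescaling, which the pipeline ignores.
#'
#' @param stack A [frame_stack()].
#' @param path Output TIFF path.
#' @param max_value Full-scale intensity; defaults to the stack maximum.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, max_value = NULL) {
  stopifnot(inherits(stack, "frame_stack"))
  if (is.null(max_value)) max_value <- max(stack$frames)
  if (max_value <= 0) max_value <- 1
  fr <- pmin(stack$frames / max_value, 1)
  pages <- lapply(seq_len(n_frames(stack)), function(i) fr[, , i])
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}
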