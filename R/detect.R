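#' Detection parameters
#'
#' Tuning knobs for well masking and embryo segmentation. Area gates are in
#' squared pixels and default to the scale of a 2 days-post-fertilization
#' embryo imaged at 3.24 um/pixel with a 2x objective.
#'
#' @param min_area,max_area Connected components with pixel area outside
#'   `[min_area, max_area]` are discarded as debris (lint, dust) or
#'   non-embryo artifacts.
#' @param max_single_area Area above which a kept blob is flagged as a
#'   probable merge of overlapping embryos (`merged-blob`); ROI placement on
#'   merged embryos is unreliable.
#' @param boundary_margin Blobs whose pixels come within this many pixels of
#'   the well-mask boundary are discarded: the well edge is darker and
#'   corrupts both thresholding and geometry.
#' @param well_fraction When no bright circular well interior can be found,
#'   the well mask falls back to a centered disc of radius
#'   `well_fraction * min(height, width) / 2`.
#' @param threshold Optional fixed intensity threshold separating embryo
#'   (dark) from background (bright). `NULL` (default) selects the
#'   threshold automatically by Otsu's method on the pixels inside the well.
#' @param closing_size Diameter in pixels of the disc structuring element
#'   used to morphologically close the embryo mask.
#' @return A named list of class `detection_params`.
#' @export
detection_params <- function(min_area = 2000, max_area = 200000,
                             max_single_area = 30000, boundary_margin = 5,
                             well_fraction = 0.95, threshold = NULL,
                             closing_size = 5) {
  stopifnot(min_area > 0, max_area > min_area, boundary_margin >= 0,
            well_fraction > 0, well_fraction <= 1, closing_size >= 1)
  structure(list(min_area = min_area, max_area = max_area,
                 max_single_area = max_single_area,
                 boundary_margin = boundary_margin,
                 well_fraction = well_fraction, threshold = threshold,
                 closing_size = closing_size),
            class = "detection_params")
}

# Otsu threshold of an intensity sample: maximizes between-class variance
# over a 256-bin histogram. Computed here (rather than on a whole image) so
# that it can be restricted to the pixels inside the well mask.
otsu_threshold <- function(v, n_bins = 256L) {
  rng <- range(v)
  if (diff(rng) == 0) return(rng[1])
  h <- tabulate(pmin(floor((v - rng[1]) / diff(rng) * n_bins) + 1L, n_bins),
                nbins = n_bins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(n_bins))
  mu_t <- mu[n_bins]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  k <- which.max(sigma_b)
  rng[1] + k / n_bins * diff(rng)
}

disc_mask <- function(dims, center, radius) {
  dr <- seq_len(dims[1]) - center[1]
  dc <- seq_len(dims[2]) - center[2]
  outer(dr^2, dc^2, "+") <= radius^2
}

#' Restrict processing to the well interior
#'
#' Finds the bright, illuminated circular interior of the microplate well in
#' a single frame and returns a filled-disc mask over it. Processing
#' downstream is limited to this disc, which excludes well walls, plate
#' surface and vignetted corners. If no convincingly circular bright region
#' exists (for example a constant frame), the mask falls back to a centered
#' disc of radius `well_fraction * min(dim)/2` and the result carries a
#' `fallback` flag.
#'
#' @param frame A single grayscale frame (numeric matrix).
#' @param params A [detection_params()] list.
#' @return An object of class `well_mask`: `mask` (logical matrix),
#'   `center` `(row, col)`, `radius` in pixels, and `fallback` flag.
#' @export
build_well_mask <- function(frame, params = detection_params()) {
  stopifnot(is.matrix(frame), length(frame) > 0)
  dims <- dim(frame)
  fallback <- function() {
    r <- params$well_fraction * min(dims) / 2
    ctr <- (dims + 1) / 2
    warning("no circular well interior found; using centered fallback disc",
            call. = FALSE)
    structure(list(mask = disc_mask(dims, ctr, r), center = ctr, radius = r,
                   fallback = TRUE), class = "well_mask")
  }
  if (diff(range(frame)) == 0) return(fallback())
  thr <- otsu_threshold(as.vector(frame))
  bright <- (frame > thr) * 1
  lab <- EBImage::bwlabel(bright)
  if (max(lab) == 0) return(fallback())
  areas <- tabulate(lab[lab > 0])
  big <- which.max(areas)
  comp <- EBImage::fillHull((lab == big) * 1) > 0
  idx <- which(comp, arr.ind = TRUE)
  ctr <- colMeans(idx)
  r <- sqrt(sum(comp) / pi)
  disc <- disc_mask(dims, ctr, r)
  # circularity: the filled component must cover most of its fitted disc
  coverage <- sum(comp & disc) / sum(disc)
  if (coverage < 0.85 || r < 0.1 * min(dims)) return(fallback())
  structure(list(mask = disc, center = ctr, radius = r, fallback = FALSE),
            class = "well_mask")
}

#' @export
print.well_mask <- function(x, ...) {
  cat(sprintf("<well_mask> center (%.1f, %.1f), radius %.1f px%s\n",
              x$center[1], x$center[2], x$radius,
              if (x$fallback) " [fallback]" else ""))
  invisible(x)
}

#' Segment embryos within the well
#'
#' Thresholds the dark embryos against the bright well background
#' (automatically via Otsu's method on well-interior pixels, or at a fixed
#' `params$threshold`), closes and hole-fills the binary mask, labels
#' 8-connected components, and removes everything that is not an embryo:
#' components smaller than `min_area` (lint, dust), larger than `max_area`,
#' or reaching within `boundary_margin` pixels of the well edge. Surviving
#' blobs are numbered 1, 2, ... by centroid position (top-to-bottom, then
#' left-to-right); these labels are the embryo identifiers used everywhere
#' downstream. Segmentation uses a single frame — the embryos are assumed
#' stationary for the duration of the video, and the ROI placed on this
#' frame is reused for all frames.
#'
#' @param frame A single grayscale frame (numeric matrix).
#' @param well A [build_well_mask()] result of matching dimensions.
#' @param params A [detection_params()] list.
#' @return A list of `embryo_blob` objects (possibly empty), each with
#'   `label`, logical `mask`, `area`, `centroid` `(row, col)` and a
#'   character vector `flags` (`"merged-blob"` when the blob is larger than
#'   `max_single_area`, suggesting overlapping embryos).
#' @export
segment_embryos <- function(frame, well, params = detection_params()) {
  stopifnot(is.matrix(frame), inherits(well, "well_mask"),
            all(dim(frame) == dim(well$mask)))
  inside <- well$mask
  thr <- if (!is.null(params$threshold)) params$threshold else
    otsu_threshold(frame[inside])
  emb <- (inside & (frame < thr)) * 1
  brush <- EBImage::makeBrush(
    as.integer(params$closing_size) %/% 2L * 2L + 1L, shape = "disc")
  emb <- EBImage::closing(emb, brush)
  emb <- EBImage::fillHull(emb)
  emb <- emb * inside
  lab <- EBImage::bwlabel(emb)
  n_comp <- max(lab)
  if (n_comp == 0) return(list())
  dr <- row(frame) - well$center[1]
  dc <- col(frame) - well$center[2]
  dist_center <- sqrt(dr^2 + dc^2)
  keep <- list()
  for (k in seq_len(n_comp)) {
    m <- lab == k
    area <- sum(m)
    if (area < params$min_area || area > params$max_area) next
    if (max(dist_center[m]) > well$radius - params$boundary_margin) next
    idx <- which(m, arr.ind = TRUE)
    flags <- character()
    if (area > params$max_single_area) {
      flags <- "merged-blob"
      warning(sprintf(
        "blob of area %d exceeds max_single_area (%g): possible overlapping embryos",
        area, params$max_single_area), call. = FALSE)
    }
    keep[[length(keep) + 1L]] <- list(mask = m, area = area,
                                      centroid = colMeans(idx),
                                      flags = flags)
  }
  if (length(keep) == 0) return(list())
  cents <- t(vapply(keep, `[[`, numeric(2), "centroid"))
  ord <- order(cents[, 1], cents[, 2])
  out <- vector("list", length(ord))
  for (i in seq_along(ord)) {
    b <- keep[[ord[i]]]
    out[[i]] <- structure(
      list(label = i, mask = b$mask, area = b$area, centroid = b$centroid,
           flags = b$flags),
      class = "embryo_blob")
  }
  out
}

#' @export
print.embryo_blob <- function(x, ...) {
  cat(sprintf("<embryo_blob> #%d: area %d px^2, centroid (%.1f, %.1f)%s\n",
              x$label, x$area, x$centroid[1], x$centroid[2],
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]")
              else ""))
  invisible(x)
}
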