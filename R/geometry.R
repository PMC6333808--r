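#' Geometric heart localization
#'
#' The heart of a 2 dpf zebrafish embryo sits on the ventral surface,
#' rostral to the yolk sac. These functions reconstruct that anatomy from
#' the embryo silhouette alone: the Feret diameter gives the body axis, the
#' maximum inscribed circle gives the yolk sac, and the heart ROI is a
#' rectangle placed tangent to the yolk circle on its head-facing side.
#'
#' @name geometry
NULL

# Boundary pixels of a logical mask: mask pixels with at least one
# 4-neighbour outside the mask (or on the image edge).
boundary_pixels <- function(mask) {
  d <- dim(mask)
  pad <- matrix(FALSE, d[1] + 2L, d[2] + 2L)
  pad[2:(d[1] + 1L), 2:(d[2] + 1L)] <- mask
  core <- pad[2:(d[1] + 1L), 2:(d[2] + 1L)]
  up    <- pad[1:d[1],        2:(d[2] + 1L)]
  down  <- pad[3:(d[1] + 2L), 2:(d[2] + 1L)]
  left  <- pad[2:(d[1] + 1L), 1:d[2]]
  right <- pad[2:(d[1] + 1L), 3:(d[2] + 2L)]
  which(core & !(up & down & left & right), arr.ind = TRUE)
}

#' Feret diameter of an embryo blob
#'
#' The Feret diameter is the longest straight line between two boundary
#' points of the silhouette — the embryo's body axis from snout to tail tip.
#' The search runs over the convex hull of the boundary (the diameter of a
#' point set is attained at hull vertices), which makes it exact at a small
#' fraction of the all-pairs cost. Ties are broken by lexicographic order
#' of the endpoint pair.
#'
#' @param blob An `embryo_blob` from [segment_embryos()], or any object
#'   with a logical `mask` matrix.
#' @return An object of class `feret_diameter`: `p_start`, `p_end`
#'   (`(row, col)`, with `p_start` lexicographically smaller) and `length`
#'   in pixels.
#' @export
compute_feret <- function(blob) {
  mask <- if (is.matrix(blob)) blob else blob$mask
  pts <- boundary_pixels(mask)
  if (nrow(pts) < 2L) {
    stop("degenerate blob: fewer than 2 boundary pixels", call. = FALSE)
  }
  hull <- grDevices::chull(pts[, 2], pts[, 1])
  hp <- unname(pts[hull, , drop = FALSE])
  if (nrow(hp) < 2L) hp <- unique(pts)
  n <- nrow(hp)
  best <- -1
  best_pair <- NULL
  for (i in seq_len(n - 1L)) {
    dr <- hp[(i + 1L):n, 1] - hp[i, 1]
    dc <- hp[(i + 1L):n, 2] - hp[i, 2]
    d2 <- dr^2 + dc^2
    for (j in which(d2 >= best - 1e-12)) {
      a <- hp[i, ]
      b <- hp[i + j, ]
      if (a[1] > b[1] || (a[1] == b[1] && a[2] > b[2])) { tmp <- a; a <- b; b <- tmp }
      pair <- c(a, b)
      if (d2[j] > best + 1e-12 ||
          (abs(d2[j] - best) <= 1e-12 && lex_less(pair, best_pair))) {
        best <- d2[j]
        best_pair <- pair
      }
    }
  }
  structure(list(p_start = best_pair[1:2], p_end = best_pair[3:4],
                 length = sqrt(best)),
            class = "feret_diameter")
}

lex_less <- function(a, b) {
  if (is.null(b)) return(TRUE)
  for (i in seq_along(a)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  FALSE
}

#' @export
print.feret_diameter <- function(x, ...) {
  cat(sprintf("<feret_diameter> %.2f px from (%g, %g) to (%g, %g)\n",
              x$length, x$p_start[1], x$p_start[2], x$p_end[1], x$p_end[2]))
  invisible(x)
}

#' Yolk-sac landmark: the maximum inscribed circle
#'
#' The yolk sac is the largest circular object within the embryo, and is
#' found as the maximum inscribed circle of the silhouette: the centre is
#' the interior pixel farthest (Euclidean distance transform) from the
#' background, and the radius is that distance. Ties among equally deep
#' pixels are broken by smallest `(row, col)`.
#'
#' @param blob An `embryo_blob` (or a logical mask matrix).
#' @return An object of class `yolk_circle` with `center` `(row, col)` and
#'   `radius` in pixels.
#' @export
find_yolk_circle <- function(blob) {
  mask <- if (is.matrix(blob)) blob else blob$mask
  d <- dim(mask)
  pad <- matrix(0, d[1] + 2L, d[2] + 2L)
  pad[2:(d[1] + 1L), 2:(d[2] + 1L)] <- mask
  dm <- EBImage::distmap(pad, metric = "euclidean")
  dm <- dm[2:(d[1] + 1L), 2:(d[2] + 1L)]
  r <- max(dm)
  if (r < 1.5) {
    stop("degenerate circle: blob is thinner than 3 px everywhere",
         call. = FALSE)
  }
  idx <- which(dm >= r - 1e-9, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  structure(list(center = as.numeric(idx[1, ]), radius = as.numeric(r)),
            class = "yolk_circle")
}

#' @export
print.yolk_circle <- function(x, ...) {
  cat(sprintf("<yolk_circle> center (%.1f, %.1f), radius %.2f px\n",
              x$center[1], x$center[2], x$radius))
  invisible(x)
}

#' Place the heart ROI tangent to the yolk circle
#'
#' The yolk sac lies rostral of the body midline, so the perpendicular
#' projection of the yolk-circle centre onto the Feret line splits the
#' diameter into a shorter (head) and a longer (tail) segment. A ray from
#' the circle centre toward the head endpoint crosses the circle perimeter
#' at the tangency point; the ROI rectangle is placed with its inner long
#' edge tangent to the circle at that point, extending outward (away from
#' the yolk), centred laterally on the tangency point. This construction is
#' equivariant under rotation and translation of the embryo, so ROI
#' placement does not depend on embryo orientation in the image plane.
#'
#' @param blob An `embryo_blob` (carried through for bookkeeping; may be
#'   `NULL`).
#' @param feret A [compute_feret()] result.
#' @param yolk A [find_yolk_circle()] result.
#' @param scale_w,scale_h ROI size as multiples of the yolk radius: width
#'   (along the tangent) `scale_w * radius`, height (outward)
#'   `scale_h * radius`. Defaults 1 and 1/3.
#' @return An object of class `heart_roi`: `center` (the tangency point,
#'   sub-pixel `(row, col)`), `width`, `height`, `angle` (radians of the
#'   tangent direction), `corners` (4 x 2 matrix, inner edge first),
#'   `outward` and `tangent` unit vectors, `scale_w`, `scale_h`, and
#'   `yolk_radius`.
#' @export
place_roi <- function(blob, feret, yolk, scale_w = 1, scale_h = 1 / 3) {
  stopifnot(inherits(feret, "feret_diameter"), inherits(yolk, "yolk_circle"),
            scale_w > 0, scale_h > 0)
  a <- as.numeric(feret$p_start)
  b <- as.numeric(feret$p_end)
  p <- as.numeric(yolk$center)
  ab <- b - a
  len <- sqrt(sum(ab^2))
  u <- ab / len
  s <- sum((p - a) * u)            # arclength of the projection from a
  if (abs(s - len / 2) < 1e-9 * max(len, 1)) {
    stop("ambiguous orientation: yolk centre projects onto the Feret midpoint",
         call. = FALSE)
  }
  head_pt <- if (s < len / 2) a else b
  v <- head_pt - p
  vn <- sqrt(sum(v^2))
  if (vn <= yolk$radius) {
    stop("geometry failure: head endpoint lies inside the yolk circle",
         call. = FALSE)
  }
  v <- v / vn                       # outward ray: yolk centre -> head
  tangent <- c(-v[2], v[1])
  T <- p + yolk$radius * v
  w <- scale_w * yolk$radius
  h <- scale_h * yolk$radius
  corners <- rbind(T - (w / 2) * tangent,
                   T + (w / 2) * tangent,
                   T + (w / 2) * tangent + h * v,
                   T - (w / 2) * tangent + h * v)
  dimnames(corners) <- list(NULL, c("row", "col"))
  structure(list(center = T, width = w, height = h,
                 angle = atan2(tangent[1], tangent[2]),
                 corners = corners, outward = v, tangent = tangent,
                 scale_w = scale_w, scale_h = scale_h,
                 yolk_radius = yolk$radius,
                 embryo_id = if (!is.null(blob$label)) blob$label else NA_integer_),
            class = "heart_roi")
}

#' @export
print.heart_roi <- function(x, ...) {
  cat(sprintf(
    "<heart_roi> %.1f x %.1f px tangent at (%.1f, %.1f), angle %.1f deg\n",
    x$width, x$height, x$center[1], x$center[2], x$angle * 180 / pi))
  invisible(x)
}

#' Rasterize a heart ROI to pixel indices
#'
#' A pixel belongs to the ROI when its centre lies inside the (oriented)
#' rectangle polygon.
#'
#' @param roi A [place_roi()] result.
#' @param dims Image dimensions `c(rows, cols)`.
#' @return Integer matrix of `(row, col)` pixel coordinates (possibly
#'   0 rows).
#' @export
roi_pixels <- function(roi, dims) {
  stopifnot(inherits(roi, "heart_roi"))
  rr <- range(roi$corners[, 1])
  cc <- range(roi$corners[, 2])
  rows <- max(1L, floor(rr[1])):min(dims[1], ceiling(rr[2]))
  cols <- max(1L, floor(cc[1])):min(dims[2], ceiling(cc[2]))
  if (length(rows) == 0L || length(cols) == 0L ||
      rr[1] > dims[1] || rr[2] < 1 || cc[1] > dims[2] || cc[2] < 1) {
    return(matrix(integer(0), 0, 2, dimnames = list(NULL, c("row", "col"))))
  }
  g <- expand.grid(row = rows, col = cols)
  dr <- g$row - roi$center[1]
  dc <- g$col - roi$center[2]
  u <- dr * roi$tangent[1] + dc * roi$tangent[2]
  v <- dr * roi$outward[1] + dc * roi$outward[2]
  inside <- abs(u) <= roi$width / 2 & v >= 0 & v <= roi$height
  as.matrix(g[inside, c("row", "col"), drop = FALSE])
}
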