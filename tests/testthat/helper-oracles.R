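# Independent brute-force oracles and small fixture builders.

# All-pairs maximum distance over boundary pixels: the O(n^2) Feret oracle.
brute_feret_length <- function(mask) {
  pts <- which(mask & !shrink_mask(mask), arr.ind = TRUE)
  if (nrow(pts) < 2) return(NA_real_)
  d2 <- as.matrix(dist(pts))^2
  sqrt(max(d2))
}

# 4-neighbour erosion used to define boundary pixels, independent of the
# package's implementation.
shrink_mask <- function(mask) {
  d <- dim(mask)
  pad <- matrix(FALSE, d[1] + 2, d[2] + 2)
  pad[2:(d[1] + 1), 2:(d[2] + 1)] <- mask
  pad[1:d[1], 2:(d[2] + 1)] & pad[3:(d[1] + 2), 2:(d[2] + 1)] &
    pad[2:(d[1] + 1), 1:d[2]] & pad[2:(d[1] + 1), 3:(d[2] + 2)] &
    pad[2:(d[1] + 1), 2:(d[2] + 1)]
}

# Max-over-foreground of min-distance-to-background: the inscribed-circle
# radius oracle (background includes a 1-px frame around the image).
brute_inscribed_radius <- function(mask) {
  d <- dim(mask)
  pad <- matrix(FALSE, d[1] + 2, d[2] + 2)
  pad[2:(d[1] + 1), 2:(d[2] + 1)] <- mask
  fg <- which(pad, arr.ind = TRUE)
  bg <- which(!pad, arr.ind = TRUE)
  best <- 0
  for (i in seq_len(nrow(fg))) {
    di <- sqrt(min((bg[, 1] - fg[i, 1])^2 + (bg[, 2] - fg[i, 2])^2))
    if (di > best) best <- di
  }
  best
}

# Random blobby mask: a few overlapping discs around a common centre,
# guaranteed connected and away from the image edge.
random_blob_mask <- function(seed, size = 64) {
  set.seed(seed)
  m <- matrix(FALSE, size, size)
  ctr <- c(size / 2, size / 2)
  n_disc <- sample(2:4, 1)
  anchor <- ctr
  for (i in seq_len(n_disc)) {
    r <- runif(1, 4, size / 6)
    off <- runif(2, -size / 8, size / 8)
    cen <- anchor + off
    cen <- pmin(pmax(cen, r + 2), size - r - 1)
    rows <- outer(seq_len(size) - cen[1], rep(1, size))
    cols <- outer(rep(1, size), seq_len(size) - cen[2])
    m <- m | (rows^2 + cols^2 <= r^2)
    anchor <- cen
  }
  m
}

make_disc_mask <- function(size, center, radius) {
  rows <- outer(seq_len(size) - center[1], rep(1, size))
  cols <- outer(rep(1, size), seq_len(size) - center[2])
  rows^2 + cols^2 <= radius^2
}

# 2-D rotation of (row, col) points about a centre.
rotate_pts <- function(p, angle, about = c(0, 0)) {
  p <- matrix(p, ncol = 2)
  dr <- p[, 1] - about[1]
  dc <- p[, 2] - about[2]
  cbind(about[1] + cos(angle) * dr - sin(angle) * dc,
        about[2] + sin(angle) * dr + cos(angle) * dc)
}

# Standard two-embryo phantom used across tests: half-scale geometry for
# speed, bin-aligned beat frequencies unless overridden.
test_phantom_spec <- function(f1 = 2.0, f2 = 2.5, noise_sd = 2, seed = 42,
                              frame_count = 165, ...) {
  size <- c(256, 256)
  phantom_spec(
    image_size = size, frame_count = frame_count, well_radius = 120,
    embryos = list(
      phantom_embryo(center = c(90, 90), a = 40, b = 14, theta = 0.7,
                     yolk_radius = 16, heart_radius = 5, f_true = f1),
      phantom_embryo(center = c(172, 168), a = 40, b = 14, theta = 3.8,
                     yolk_radius = 16, heart_radius = 5, f_true = f2)),
    noise_sd = noise_sd, seed = seed, ...)
}

test_params <- function(...) phantom_detection_params(c(256, 256), ...)
test_config <- function(...) {
  run_config(detection = test_params(), ...)
}

# Match each processed embryo to its ground-truth row by ROI target point.
truth_row_for <- function(truth, roi) {
  which.min((truth$target_row - roi$center[1])^2 +
              (truth$target_col - roi$center[2])^2)
}
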