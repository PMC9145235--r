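# Shared fixtures: a small, fast synthetic scene plus brute-force
# geometry oracles that are independent of the package's own algorithms.

# a compact section (3 mm radius, coarser pixels) for unit tests
small_shape <- function(shape = "round") {
  section_shape_spec(shape, outer_radius = 3, resolution = 27.1)
}

small_bundles <- function(pz = 10, iz = 12) {
  bundle_spec(pz_count = pz, iz_count = iz,
              pz_radius_mm = c(0.13, 0.01), iz_radius_mm = c(0.17, 0.012),
              min_gap_mm = 0.5)
}

small_scene <- function(seed = 1, shape = "round", pz = 10, iz = 12) {
  generate_cross_section(small_shape(shape), small_bundles(pz, iz),
                         seed = seed)
}

# digital disk pixel set of radius r_px centred in a (2r+20)^2 frame
disk_pixels <- function(r_px, cx = r_px + 10, cy = r_px + 10) {
  n <- ceiling(2 * r_px + 20)
  px <- as.matrix(expand.grid(x = seq_len(n), y = seq_len(n)))
  px[(px[, 1] - 0.5 - cx)^2 + (px[, 2] - 0.5 - cy)^2 <= r_px^2, ,
     drop = FALSE]
}

# random connected-ish pixel blob (unique pixels, may be ragged)
random_blob <- function(n_px = 30, extent = 12L) {
  unique(cbind(sample.int(extent, n_px, replace = TRUE),
               sample.int(extent, n_px, replace = TRUE)))
}

# brute-force convex hull area: O(n^3) edge test (a directed pair is a
# hull edge iff every point lies on its left), polygon assembled by angle
# sort of the hull vertices
oracle_hull_area <- function(pts) {
  pts <- unique(pts)
  n <- nrow(pts)
  if (n < 3) return(0)
  on_hull <- logical(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    cr <- (pts[j, 1] - pts[i, 1]) * (pts[, 2] - pts[i, 2]) -
      (pts[j, 2] - pts[i, 2]) * (pts[, 1] - pts[i, 1])
    if (all(cr <= 1e-9)) on_hull[c(i, j)] <- TRUE
  }
  hp <- pts[on_hull, , drop = FALSE]
  cen <- colMeans(hp)
  hp <- hp[order(atan2(hp[, 2] - cen[2], hp[, 1] - cen[1])), , drop = FALSE]
  x <- hp[, 1]; y <- hp[, 2]
  j <- c(2:nrow(hp), 1)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

# brute-force minimal enclosing circle: best of all 2-point and 3-point
# candidate circles that contain every point
oracle_mec_radius <- function(pts) {
  pts <- unique(pts)
  n <- nrow(pts)
  best <- Inf
  contains_all <- function(c0, r2)
    all((pts[, 1] - c0[1])^2 + (pts[, 2] - c0[2])^2 <= r2 * (1 + 1e-9) + 1e-9)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    c0 <- (pts[i, ] + pts[j, ]) / 2
    r2 <- sum((pts[i, ] - c0)^2)
    if (r2 < best && contains_all(c0, r2)) best <- r2
    if (n >= 3) for (k in seq_len(n)) {
      if (k <= j) next
      a <- pts[i, ]; b <- pts[j, ]; cc <- pts[k, ]
      d <- 2 * (a[1] * (b[2] - cc[2]) + b[1] * (cc[2] - a[2]) +
                  cc[1] * (a[2] - b[2]))
      if (abs(d) < 1e-12) next
      ux <- (sum(a^2) * (b[2] - cc[2]) + sum(b^2) * (cc[2] - a[2]) +
               sum(cc^2) * (a[2] - b[2])) / d
      uy <- (sum(a^2) * (cc[1] - b[1]) + sum(b^2) * (a[1] - cc[1]) +
               sum(cc^2) * (b[1] - a[1])) / d
      r2 <- sum((a - c(ux, uy))^2)
      if (r2 < best && contains_all(c(ux, uy), r2)) best <- r2
    }
  }
  sqrt(best)
}

# greedy one-to-one matching of truth and detected centroids; returns the
# number matched within tol_px
match_centroids <- function(truth_xy, det_xy, tol_px = 1) {
  if (nrow(truth_xy) == 0 || nrow(det_xy) == 0) return(0L)
  d <- as.matrix(stats::dist(rbind(truth_xy, det_xy)))
  d <- d[seq_len(nrow(truth_xy)), nrow(truth_xy) + seq_len(nrow(det_xy)),
         drop = FALSE]
  matched <- 0L
  while (TRUE) {
    m <- which(d == min(d), arr.ind = TRUE)[1, ]
    if (d[m[1], m[2]] > tol_px) break
    matched <- matched + 1L
    d[m[1], ] <- Inf; d[, m[2]] <- Inf
    if (all(!is.finite(d))) break
  }
  matched
}
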