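## Synthetic cross-section generator.
##
## Coordinate conventions used throughout the package:
##  * the pixel grid is a matrix indexed [ix, iy] (x = first dimension,
##    matching EBImage); pixel (ix, iy) covers the continuous square
##    [ix-1, ix] x [iy-1, iy] in pixel units, so its centre is
##    (ix - 0.5, iy - 0.5);
##  * physical coordinates are pixel units times resolution/1000 (mm).

res_mm <- function(resolution) resolution / 1000

#' Construct a section image object
#'
#' @param pixels Integer matrix of 8-bit intensities (0-255), indexed
#'   `[x, y]`.
#' @param resolution Pixel size in micrometres per pixel.
#' @return A `section_image` object.
#' @export
section_image <- function(pixels, resolution) {
  if (!is.matrix(pixels)) stopf("pixels must be a matrix")
  if (resolution <= 0) stopf("resolution must be positive")
  structure(list(pixels = pixels, resolution = resolution),
            class = "section_image")
}

#' @export
print.section_image <- function(x, ...) {
  cat(sprintf("<section_image> %d x %d px at %.2f um/px (%.2f x %.2f mm)\n",
              nrow(x$pixels), ncol(x$pixels), x$resolution,
              nrow(x$pixels) * res_mm(x$resolution),
              ncol(x$pixels) * res_mm(x$resolution)))
  invisible(x)
}

## Boolean outline of the section on a pixel-centre grid, in mm coordinates
## centred on the primary disk. Returns a logical matrix [ix, iy].
shape_outline <- function(spec, xc, yc) {
  R <- spec$outer_radius
  X <- matrix(xc, nrow = length(xc), ncol = length(yc))
  Y <- matrix(yc, nrow = length(xc), ncol = length(yc), byrow = TRUE)
  r2 <- X^2 + Y^2
  inside <- r2 <= R^2
  if (spec$shape == "round") return(inside)
  if (spec$shape == "crescent") {
    ## carve a secondary disk biting notch_depth into the +x side
    rc <- spec$eccentricity * R
    cx <- R + rc - spec$notch_depth
    inside & ((X - cx)^2 + Y^2 > rc^2)
  } else if (spec$shape == "bell") {
    ## straight chord cut: dome with a flattened base
    inside & (X <= R - spec$notch_depth)
  } else if (spec$shape == "horseshoe") {
    ## carve a wedge of angular width notch_angle, depth notch_depth
    ang <- atan2(Y, X)
    notch <- abs(ang) < spec$notch_angle / 2 &
      r2 > (R - spec$notch_depth)^2
    inside & !notch
  } else { # irregular: low-order radial harmonics (uses RNG)
    ang <- atan2(Y, X)
    rad <- sqrt(r2)
    rr <- rep(1, length(ang))
    dim(rr) <- dim(ang)
    for (k in 2:5) {
      amp <- spec$harmonics / k
      phi <- stats::runif(1, 0, 2 * pi)
      rr <- rr + amp * cos(k * ang + phi)
    }
    rad <= R * rr
  }
}

## Depth (mm) of each tissue pixel centre from the section boundary,
## via Euclidean distance transform. Background pixels get 0.
depth_map_mm <- function(mask, resolution) {
  d <- EBImage::distmap(EBImage::Image(mask * 1))
  d <- as.numeric(d)
  dim(d) <- dim(mask)
  pmax(d - 0.5, 0) * res_mm(resolution)
}

place_bundles <- function(depth, mask, spec, bspec, max_attempts = 2000L) {
  rm <- res_mm(spec$resolution)
  n_total <- bspec$pz_count + bspec$iz_count
  section_area_mm2 <- sum(mask) * rm^2
  zones <- c(rep("PZ", bspec$pz_count), rep("IZ", bspec$iz_count))
  mu_r <- ifelse(zones == "PZ", bspec$pz_radius_mm[1], bspec$iz_radius_mm[1])
  sd_r <- ifelse(zones == "PZ", bspec$pz_radius_mm[2], bspec$iz_radius_mm[2])
  ## hard area bound: disks alone cannot exceed the section area
  cum_area <- cumsum(pi * mu_r^2)
  if (any(cum_area > section_area_mm2)) {
    k <- which(cum_area > section_area_mm2)[1]
    stopf("infeasible packing: bundle %d (%s) cannot be placed (cumulative bundle area %.1f mm^2 exceeds section area %.1f mm^2)",
          k, zones[k], cum_area[k], section_area_mm2)
  }
  ez <- bspec$ez_mm; w <- bspec$pz_width_mm; so <- bspec$boundary_standoff_mm
  pz_idx <- which(depth > ez & depth <= ez + w - so)
  iz_idx <- which(depth >= ez + w + so)
  nx <- nrow(mask)
  xs <- numeric(n_total); ys <- numeric(n_total); rs <- numeric(n_total)
  for (i in seq_len(n_total)) {
    placed <- FALSE
    for (att in seq_len(max_attempts)) {
      ## radius truncated at +/- 2.5 sd so min_gap can guarantee
      ## non-overlap between neighbouring bundles
      rb <- max(0.02, min(mu_r[i] + 2.5 * sd_r[i],
                          max(mu_r[i] - 2.5 * sd_r[i],
                              stats::rnorm(1, mu_r[i], sd_r[i]))))
      pool <- if (zones[i] == "PZ") pz_idx else iz_idx
      if (length(pool) == 0L) break
      j <- pool[sample.int(length(pool), 1L)]
      ix <- ((j - 1L) %% nx) + 1L
      iy <- ((j - 1L) %/% nx) + 1L
      px <- (ix - 1) + stats::runif(1)
      py <- (iy - 1) + stats::runif(1)
      dmm <- depth[j]
      lo <- if (zones[i] == "PZ") ez + rb else ez + w + so
      hi <- if (zones[i] == "PZ") ez + w - so else Inf
      if (dmm < lo + 0.01 || dmm > hi) next
      if (i > 1L) {
        dx <- (px - xs[seq_len(i - 1L)]) * rm
        dy <- (py - ys[seq_len(i - 1L)]) * rm
        if (min(dx * dx + dy * dy) < bspec$min_gap_mm^2) next
      }
      xs[i] <- px; ys[i] <- py; rs[i] <- rb
      placed <- TRUE
      break
    }
    if (!placed)
      stopf("infeasible packing: bundle %d (%s) could not be placed within %d attempts",
            i, zones[i], max_attempts)
  }
  data.frame(id = seq_len(n_total), zone = zones,
             x_px = xs, y_px = ys, radius_mm = rs,
             stringsAsFactors = FALSE)
}

rasterize_bundles <- function(dim_xy, placements, resolution) {
  rm <- res_mm(resolution)
  bm <- matrix(FALSE, dim_xy[1], dim_xy[2])
  area_px <- integer(nrow(placements))
  for (i in seq_len(nrow(placements))) {
    px <- placements$x_px[i]; py <- placements$y_px[i]
    rpx <- placements$radius_mm[i] / rm
    ix <- max(1L, floor(px - rpx)):min(dim_xy[1], ceiling(px + rpx) + 1L)
    iy <- max(1L, floor(py - rpx)):min(dim_xy[2], ceiling(py + rpx) + 1L)
    cx <- ix - 0.5; cy <- iy - 0.5
    d2 <- outer(cx - px, cy - py, function(a, b) a * a + b * b)
    hit <- d2 <= rpx^2
    area_px[i] <- sum(hit)
    sub <- bm[ix, iy, drop = FALSE]
    sub[hit] <- TRUE
    bm[ix, iy] <- sub
  }
  list(mask = bm, area_px = area_px)
}

#' Generate a synthetic cross-section image with ground truth
#'
#' Renders a section of the requested shape with three intensity bands
#' (background 0, tissue 120, bundles 220) plus additive Gaussian noise,
#' and plants vascular bundles in two depth bands: a periphery annulus just
#' inside the epidermis and the remaining inner disk. Placement is by
#' rejection sampling with a minimum centroid gap; an infeasible request
#' raises an error naming the first unplaceable bundle.
#'
#' @param shape A [section_shape_spec()].
#' @param bundles A [bundle_spec()].
#' @param seed Integer seed; identical seeds give bit-identical images.
#' @param noise_sd Standard deviation of the additive Gaussian intensity
#'   noise (8-bit units).
#' @param margin_mm Background margin around the section, mm.
#' @return A list with elements `image` (a [section_image()]) and `truth`
#'   (class `section_truth`: per-bundle records, planted zone boundary
#'   depths, the section mask and the seed).
#' @export
#' @examples
#' sc <- generate_cross_section(
#'   section_shape_spec("round", outer_radius = 3, resolution = 27),
#'   bundle_spec(pz_count = 10, iz_count = 12), seed = 1)
#' table(sc$truth$bundles$zone)
generate_cross_section <- function(shape, bundles, seed,
                                   noise_sd = 8, margin_mm = 0.3) {
  stopifnot(inherits(shape, "section_shape_spec"),
            inherits(bundles, "bundle_spec"))
  rm <- res_mm(shape$resolution)
  half <- shape$outer_radius * (1 + shape$harmonics) + margin_mm
  n <- 2L * as.integer(ceiling(half / rm))
  withr::with_seed(seed, {
    centres <- ((seq_len(n) - 0.5) - n / 2) * rm
    mask <- shape_outline(shape, centres, centres)
    depth <- depth_map_mm(mask, shape$resolution)
    pl <- place_bundles(depth, mask, shape, bundles)
    ras <- rasterize_bundles(c(n, n), pl, shape$resolution)
    img <- matrix(0, n, n)
    img[mask] <- 120
    img[ras$mask] <- 220
    img <- img + stats::rnorm(n * n, 0, noise_sd)
    img <- matrix(as.integer(pmin(255, pmax(0, round(img)))), n, n)
  })
  pl$area_px <- ras$area_px
  pl$depth_mm <- depth[cbind(pmin(n, ceiling(pl$x_px)),
                             pmin(n, ceiling(pl$y_px)))]
  truth <- structure(list(
    bundles = pl,
    ez_depth_mm = bundles$ez_mm,
    pz_depth_mm = bundles$ez_mm + bundles$pz_width_mm,
    section_mask = mask,
    section_area_px = sum(mask),
    resolution = shape$resolution,
    seed = seed), class = "section_truth")
  list(image = section_image(img, shape$resolution), truth = truth)
}
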