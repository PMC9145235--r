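## Section segmentation, bundle detection and zone partitioning.
## Foreground connectivity is 8-connected (diagonal-touching pixels join),
## background 4-connected; labels are compact positive integers.

## Otsu threshold on an 8-bit intensity vector: maximises between-class
## variance over the 0..255 histogram. Returns NA for a constant input.
otsu_threshold <- function(v) {
  h <- as.numeric(tabulate(as.integer(v) + 1L, nbins = 256L))
  n <- sum(h)
  lev <- 0:255
  if (sum(h > 0) < 2) return(NA_real_)
  w1 <- cumsum(h)
  m1 <- cumsum(h * lev)
  mt <- m1[256]
  w2 <- n - w1
  keep <- w1 > 0 & w2 > 0
  mu1 <- m1 / w1
  mu2 <- (mt - m1) / w2
  bc <- w1 * w2 * (mu1 - mu2)^2
  bc[!keep] <- -Inf
  lev[which.max(bc)]
}

## 8-connected labelling: EBImage's 4-connected labelling plus a
## union-find merge over diagonal-touching label pairs.
label8 <- function(M) {
  L <- EBImage::bwlabel(EBImage::Image(M * 1))
  L <- matrix(as.integer(L), nrow(M), ncol(M))
  nl <- max(L)
  if (nl < 2) return(L)
  w <- nrow(L); h <- ncol(L)
  a1 <- L[1:(w - 1), 1:(h - 1)]; b1 <- L[2:w, 2:h]
  a2 <- L[2:w, 1:(h - 1)];       b2 <- L[1:(w - 1), 2:h]
  pa <- c(a1[a1 > 0 & b1 > 0 & a1 != b1], a2[a2 > 0 & b2 > 0 & a2 != b2])
  pb <- c(b1[a1 > 0 & b1 > 0 & a1 != b1], b2[a2 > 0 & b2 > 0 & a2 != b2])
  if (length(pa)) {
    parent <- seq_len(nl)
    find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
    for (i in seq_along(pa)) {
      ra <- find(pa[i]); rb <- find(pb[i])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
    root <- vapply(seq_len(nl), find, 0L)
    compact <- match(root, sort(unique(root)))
    L[L > 0] <- compact[L[L > 0]]
  }
  L
}

#' Segment the section tissue from the background
#'
#' Thresholds the image (Otsu by default), keeps the largest 8-connected
#' above-threshold component and fills its holes. The result is invariant
#' to padding the image with background.
#'
#' @param image A [section_image()].
#' @param threshold_policy `"otsu"` or a single number: the fixed
#'   threshold in 8-bit units (pixels strictly above it are foreground).
#' @return A `section_mask` object: logical matrix `mask`, `centroid_px`,
#'   `resolution`.
#' @export
segment_section <- function(image, threshold_policy = "otsu") {
  stopifnot(inherits(image, "section_image"))
  img <- image$pixels
  if (identical(threshold_policy, "otsu")) {
    if (length(unique(as.integer(img))) == 1L) {
      if (img[1] > 0) thr <- -1 else stopf("empty section: no foreground pixels")
    } else thr <- otsu_threshold(img)
  } else if (is.numeric(threshold_policy) && length(threshold_policy) == 1L) {
    thr <- threshold_policy
  } else stopf("threshold_policy must be 'otsu' or a single number")
  fg <- img > thr
  if (!any(fg)) stopf("empty section: no foreground pixels")
  L <- label8(fg)
  sizes <- tabulate(L[L > 0])
  keep <- which.max(sizes)
  mask <- L == keep
  mask <- EBImage::fillHull(EBImage::Image(mask * 1)) > 0
  mask <- matrix(as.logical(mask), nrow(img), ncol(img))
  idx <- which(mask, arr.ind = TRUE)
  structure(list(mask = mask,
                 centroid_px = c(mean(idx[, 1]) - 0.5, mean(idx[, 2]) - 0.5),
                 resolution = image$resolution),
            class = "section_mask")
}

#' @export
print.section_mask <- function(x, ...) {
  cat(sprintf("<section_mask> %d px (%.2f mm^2)\n", sum(x$mask),
              sum(x$mask) * res_mm(x$resolution)^2))
  invisible(x)
}

#' Detect vascular-bundle candidate regions
#'
#' Thresholds the bundle intensity band inside the section mask (Otsu on
#' the within-mask histogram), labels 8-connected components and keeps the
#' regions that pass three validity filters: an area window
#' `[min_area, max_area]` (mm^2) and a minimum solidity (area / convex
#' area). Failing candidates are reported in a `rejects` table rather
#' than split.
#'
#' @param image A [section_image()].
#' @param mask The [segment_section()] result for the same image.
#' @param min_area,max_area Area window, mm^2.
#' @param min_solidity Minimum solidity, in (0, 1].
#' @return A `bundle_set`: data.frame `regions` (id, centroid, areas,
#'   solidity, zone), list `pixels` of per-region coordinate matrices,
#'   data.frame `rejects` with a `reason` column, and `resolution`.
#' @export
detect_bundles <- function(image, mask, min_area = 0.005, max_area = 0.5,
                           min_solidity = 0.5) {
  stopifnot(inherits(image, "section_image"), inherits(mask, "section_mask"))
  if (min_area >= max_area) stopf("min_area must be < max_area")
  img <- image$pixels
  inm <- img[mask$mask]
  thr <- otsu_threshold(inm)
  if (is.na(thr)) stopf("cannot separate bundles: constant intensity in mask")
  cand <- (img > thr) & mask$mask
  s2 <- res_mm(image$resolution)^2
  L <- label8(cand)
  nl <- max(L)
  if (nl == 0L)
    return(structure(list(regions = empty_regions(), pixels = list(),
                          rejects = empty_regions(reason = TRUE),
                          resolution = image$resolution),
                     class = "bundle_set"))
  idx <- which(L > 0, arr.ind = TRUE)
  lab <- L[L > 0]
  ord <- order(lab)
  idx <- idx[ord, , drop = FALSE]; lab <- lab[ord]
  splits <- split(seq_len(nrow(idx)), lab)
  rows <- vector("list", nl); pixl <- vector("list", nl)
  for (k in seq_len(nl)) {
    px <- idx[splits[[k]], , drop = FALSE]
    g <- region_geometry(px, image$resolution)
    rows[[k]] <- data.frame(id = k, x_px = g$centroid_px[1],
                            y_px = g$centroid_px[2],
                            area_px = nrow(px), area_mm2 = g$A,
                            solidity = g$CAR, zone = "unassigned",
                            stringsAsFactors = FALSE)
    pixl[[k]] <- px
  }
  tab <- do.call(rbind, rows)
  ok <- tab$area_mm2 >= min_area & tab$area_mm2 <= max_area &
    tab$solidity >= min_solidity
  rejects <- tab[!ok, , drop = FALSE]
  if (nrow(rejects)) {
    rejects$reason <- ifelse(rejects$area_mm2 < min_area, "below_min_area",
                      ifelse(rejects$area_mm2 > max_area, "above_max_area",
                             "low_solidity"))
  } else rejects$reason <- character(0)
  regions <- tab[ok, , drop = FALSE]
  pixl <- pixl[ok]
  if (nrow(regions)) {
    regions$id <- seq_len(nrow(regions))
    rownames(regions) <- NULL
  }
  structure(list(regions = regions, pixels = pixl, rejects = rejects,
                 resolution = image$resolution),
            class = "bundle_set")
}

empty_regions <- function(reason = FALSE) {
  out <- data.frame(id = integer(0), x_px = numeric(0), y_px = numeric(0),
                    area_px = integer(0), area_mm2 = numeric(0),
                    solidity = numeric(0), zone = character(0),
                    stringsAsFactors = FALSE)
  if (reason) out$reason <- character(0)
  out
}

#' @export
print.bundle_set <- function(x, ...) {
  cat(sprintf("<bundle_set> %d regions (%d rejected)\n",
              nrow(x$regions), nrow(x$rejects)))
  invisible(x)
}

#' Partition the section into epidermis, periphery and inner zones
#'
#' The epidermis (EZ) is the boundary band of depth `ez_thickness`; the
#' PZ/IZ boundary is placed either at the first valley of the smoothed
#' radial density of bundle centroids after the peripheral peak
#' (`"density_valley"`, the default) or at a fixed depth from the section
#' contour (`pz_policy = list(fixed_depth = d)`). Labels partition the
#' mask exactly: 1 = EZ, 2 = PZ, 3 = IZ (0 = background).
#'
#' @param mask A `section_mask`.
#' @param bundles A `bundle_set` (used only by the density-valley policy).
#' @param ez_thickness Epidermis depth, mm. Default 0.08 mm, near the
#'   population median epidermis thickness of maize shank sections.
#' @param pz_policy `"density_valley"` or `list(fixed_depth = d)` (mm).
#' @param valley_bw Kernel bandwidth for the centroid-depth density, mm.
#' @param fallback_depth PZ width used when no valley exists, mm (the
#'   boundary is then at `ez_thickness + fallback_depth`).
#' @return A `zone_partition`: integer `labels` matrix, boundary depths
#'   `ez_depth_mm` and `pz_depth_mm`, the policy actually used, the
#'   section centroid and `resolution`.
#' @export
partition_zones <- function(mask, bundles = NULL, ez_thickness = 0.08,
                            pz_policy = "density_valley",
                            valley_bw = 0.25, fallback_depth = 1.0) {
  stopifnot(inherits(mask, "section_mask"))
  D <- depth_map_mm(mask$mask, mask$resolution)
  inradius <- max(D)
  if (ez_thickness >= inradius)
    stopf("ez_thickness (%.3f mm) must be smaller than the minimal inradius (%.3f mm)",
          ez_thickness, inradius)
  if (is.list(pz_policy) && !is.null(pz_policy$fixed_depth)) {
    d_b <- pz_policy$fixed_depth
    if (d_b <= ez_thickness || d_b >= inradius)
      stopf("fixed_depth must lie in (ez_thickness, inradius)")
    policy <- sprintf("fixed_depth(%g)", d_b)
  } else if (identical(pz_policy, "density_valley")) {
    if (is.null(bundles) || nrow(bundles$regions) < 3)
      stopf("density_valley policy needs a bundle_set with >= 3 regions")
    cd <- D[cbind(pmax(1L, ceiling(bundles$regions$x_px)),
                  pmax(1L, ceiling(bundles$regions$y_px)))]
    d_b <- density_valley_depth(cd, valley_bw, inradius)
    if (is.na(d_b)) d_b <- ez_thickness + fallback_depth
    policy <- "density_valley"
  } else stopf("unknown pz_policy")
  lab <- matrix(0L, nrow(mask$mask), ncol(mask$mask))
  lab[mask$mask] <- 3L
  lab[mask$mask & D <= d_b] <- 2L
  lab[mask$mask & D <= ez_thickness] <- 1L
  structure(list(labels = lab, ez_depth_mm = ez_thickness,
                 pz_depth_mm = d_b, policy = policy,
                 centroid_px = mask$centroid_px,
                 resolution = mask$resolution),
            class = "zone_partition")
}

## First substantial local minimum of the smoothed depth density after
## the first (peripheral) local maximum. A candidate minimum only counts
## as a valley when the density rises again by at least 20% of the peak
## height (sampling wobble in the sparse inner region rebounds by far
## less); a monotone decline beyond the peak has no valley and returns
## NA, upon which the caller falls back to a fixed PZ width.
density_valley_depth <- function(depths, bw, inradius) {
  de <- stats::density(depths, bw = bw, from = 0, to = inradius, n = 512)
  y <- de$y
  n <- length(y)
  dy <- diff(y)
  peak <- NA_integer_
  for (i in seq_len(n - 2)) {
    if (dy[i] > 0 && dy[i + 1] <= 0) { peak <- i + 1L; break }
  }
  if (is.na(peak)) return(NA_real_)
  for (i in peak:(n - 2)) {
    if (dy[i] < 0 && dy[i + 1] >= 0) {
      rebound <- max(y[(i + 1):n]) - y[i + 1]
      if (rebound >= 0.2 * y[peak]) return(de$x[i + 1L])
    }
  }
  NA_real_
}

#' @export
print.zone_partition <- function(x, ...) {
  cat(sprintf("<zone_partition> EZ depth %.3f mm, PZ/IZ boundary %.3f mm (%s)\n",
              x$ez_depth_mm, x$pz_depth_mm, x$policy))
  invisible(x)
}

#' Assign bundles to zones by the centroid rule
#'
#' A bundle belongs to the zone containing its centroid pixel; a centroid
#' falling in the epidermis band maps to PZ (bundles are never epidermal).
#' Ties on a boundary pixel go to the inner of the two zones by
#' construction of the label raster.
#'
#' @param bundles A `bundle_set`.
#' @param partition A `zone_partition`.
#' @return The `bundle_set` with the `zone` column filled with
#'   `"PZ"`/`"IZ"`.
#' @export
assign_zone <- function(bundles, partition) {
  stopifnot(inherits(bundles, "bundle_set"),
            inherits(partition, "zone_partition"))
  if (nrow(bundles$regions) == 0L) return(bundles)
  ix <- pmax(1L, ceiling(bundles$regions$x_px))
  iy <- pmax(1L, ceiling(bundles$regions$y_px))
  lab <- partition$labels[cbind(ix, iy)]
  if (any(lab == 0L))
    stopf("bundle centroid outside the section (bundle %d)",
          bundles$regions$id[which(lab == 0L)[1]])
  bundles$regions$zone <- c("PZ", "PZ", "IZ")[lab]
  bundles
}
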