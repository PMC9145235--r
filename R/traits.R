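## The 36-trait computation over a section mask, zone partition and
## zone-assigned bundle set.

#' Mean radial thickness of a functional zone
#'
#' Samples rays from the section centroid at `n_rays` angles, reading the
#' zone label along each ray in half-pixel steps. `EZ` and `PZ` thickness
#' are the mean run length of the band along the rays; `IZ` thickness is
#' the mean radial distance from the centroid to the PZ/IZ boundary.
#'
#' @param partition A `zone_partition`.
#' @param zone One of `"EZ"`, `"PZ"`, `"IZ"`.
#' @param n_rays Number of ray directions.
#' @return Thickness in mm.
#' @export
zone_thickness <- function(partition, zone = c("EZ", "PZ", "IZ"),
                           n_rays = 360L) {
  stopifnot(inherits(partition, "zone_partition"))
  zone <- match.arg(zone)
  zl <- c(EZ = 1L, PZ = 2L, IZ = 3L)[[zone]]
  lab <- partition$labels
  if (!any(lab == zl)) stopf("zone %s is empty in this partition", zone)
  cx <- partition$centroid_px[1]; cy <- partition$centroid_px[2]
  nx <- nrow(lab); ny <- ncol(lab)
  step <- 0.5
  rmax <- sqrt(nx^2 + ny^2) / 2 + 2
  radii <- seq(step, rmax, by = step)
  ang <- (seq_len(n_rays) - 1) * 2 * pi / n_rays
  s <- res_mm(partition$resolution)
  vals <- numeric(n_rays)
  for (a in seq_len(n_rays)) {
    px <- cx + radii * cos(ang[a])
    py <- cy + radii * sin(ang[a])
    ix <- ceiling(px); iy <- ceiling(py)
    ok <- ix >= 1L & ix <= nx & iy >= 1L & iy <= ny
    l <- integer(length(radii))
    l[ok] <- lab[cbind(ix[ok], iy[ok])]
    vals[a] <- if (zone == "IZ") {
      k <- which(l == 3L)
      if (length(k)) radii[max(k)] * s else 0
    } else sum(l == zl) * step * s
  }
  mean(vals[vals > 0])
}

#' Compute the 36-trait vector of a section
#'
#' Populates every trait in [trait_registry()] from the section mask, the
#' zone partition and the zone-assigned bundles, in physical units.
#' Per-zone aggregates run over the bundles assigned to that zone;
#' `VB_*ave` traits are unweighted means over all bundles;
#' `VB_LWR = VB_LAave / VB_SAave`; `SRVB` is the mean nearest-neighbour
#' centroid distance divided by the mean bundle equivalent diameter;
#' `ARIVB` is the mean bundle area in PZ divided by the mean bundle area
#' in IZ. A zone with no bundles reports its averages as `NA` and its
#' densities as 0; a section with no bundles at all is an error.
#'
#' @param mask A `section_mask`.
#' @param partition A `zone_partition` over the same mask.
#' @param bundles A zone-assigned `bundle_set` (see [assign_zone()]).
#' @param resolution Pixel size, micrometres per pixel.
#' @return Named numeric vector of length 36 (names as in
#'   [trait_names()]).
#' @export
compute_trait_vector <- function(mask, partition, bundles,
                                 resolution = mask$resolution) {
  stopifnot(inherits(mask, "section_mask"),
            inherits(partition, "zone_partition"),
            inherits(bundles, "bundle_set"))
  nb <- nrow(bundles$regions)
  if (nb == 0L) stopf("no bundles: cannot compute trait vector")
  if (any(bundles$regions$zone == "unassigned"))
    stopf("bundles must be zone-assigned first (see assign_zone)")
  s <- res_mm(resolution)
  px_mask <- which(mask$mask, arr.ind = TRUE)
  gz <- region_geometry(px_mask, resolution)

  ## per-bundle geometry
  bg <- lapply(bundles$pixels, region_geometry, resolution = resolution)
  A <- vapply(bg, `[[`, 0, "A");   CA <- vapply(bg, `[[`, 0, "CA")
  CCA <- vapply(bg, `[[`, 0, "CCA"); P <- vapply(bg, `[[`, 0, "P")
  LA <- vapply(bg, `[[`, 0, "LA"); SA <- vapply(bg, `[[`, 0, "SA")
  CAR <- vapply(bg, `[[`, 0, "CAR")
  zone <- bundles$regions$zone
  in_pz <- zone == "PZ"; in_iz <- zone == "IZ"

  zone_area <- function(z) sum(partition$labels == z) * s^2
  ez_a <- zone_area(1L); pz_a <- zone_area(2L); iz_a <- zone_area(3L)

  mean_or_na <- function(v) if (length(v)) mean(v) else NA_real_
  dens <- function(n, a) if (a > 0) n / a else 0

  ## nearest-neighbour separation (mm)
  srvb <- NA_real_
  if (nb >= 2) {
    cx <- bundles$regions$x_px * s; cy <- bundles$regions$y_px * s
    dm <- as.matrix(stats::dist(cbind(cx, cy)))
    diag(dm) <- Inf
    nnd <- apply(dm, 1, min)
    srvb <- mean(nnd) / mean(2 * sqrt(A / pi))
  }

  out <- c(
    SZ_SA = gz$SA, SZ_P = gz$P, SZ_LWR = gz$LWR, SZ_LA = gz$LA,
    SZ_CCA = gz$CCA, SZ_CA = gz$CA, SZ_A = gz$A,
    EZ_T = zone_thickness(partition, "EZ"), EZ_A = ez_a,
    PZ_VB_N = sum(in_pz), PZ_VB_D = dens(sum(in_pz), pz_a),
    PZ_VB_CAR = mean_or_na(CAR[in_pz]),
    PZ_VB_CA = if (any(in_pz)) sum(CA[in_pz]) else NA_real_,
    PZ_VB_A = if (any(in_pz)) sum(A[in_pz]) else NA_real_,
    PZ_T = zone_thickness(partition, "PZ"), PZ_A = pz_a,
    IZ_VB_N = sum(in_iz), IZ_VB_D = dens(sum(in_iz), iz_a),
    IZ_VB_CAR = mean_or_na(CAR[in_iz]),
    IZ_VB_CA = if (any(in_iz)) sum(CA[in_iz]) else NA_real_,
    IZ_VB_A = if (any(in_iz)) sum(A[in_iz]) else NA_real_,
    IZ_T = zone_thickness(partition, "IZ"), IZ_A = iz_a,
    VB_SAave = mean(SA), VB_Pave = mean(P), VB_N = nb,
    VB_LWR = mean(LA) / mean(SA), VB_LAave = mean(LA),
    VB_D = nb / gz$A, VB_CCAave = mean(CCA), VB_CAR = mean(CAR),
    VB_CAave = mean(CA), VB_Aave = mean(A), VB_A = sum(A),
    SRVB = srvb,
    ARIVB = if (any(in_pz) && any(in_iz)) mean(A[in_pz]) / mean(A[in_iz])
            else NA_real_
  )
  stopifnot(identical(names(out), trait_names()))
  out
}

#' Run the full phenotyping pipeline on one section image
#'
#' Convenience wrapper: segment, detect, partition, assign, measure.
#'
#' @param image A [section_image()].
#' @param ez_thickness,pz_policy Passed to [partition_zones()].
#' @param ... Passed to [detect_bundles()].
#' @return List with `mask`, `bundles`, `partition` and `traits` (the
#'   36-trait vector).
#' @export
phenotype_section <- function(image, ez_thickness = 0.08,
                              pz_policy = "density_valley", ...) {
  mask <- segment_section(image)
  bundles <- detect_bundles(image, mask, ...)
  partition <- partition_zones(mask, bundles, ez_thickness = ez_thickness,
                               pz_policy = pz_policy)
  bundles <- assign_zone(bundles, partition)
  traits <- compute_trait_vector(mask, partition, bundles,
                                 image$resolution)
  list(mask = mask, bundles = bundles, partition = partition,
       traits = traits)
}
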