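# Segmentation, bundle detection and zone partitioning against the
# generator's ground truth.

test_that("segment_section recovers the section area and handles edge cases", {
  sc <- small_scene(seed = 4)
  mask <- segment_section(sc$image)
  expect_lt(abs(sum(mask$mask) / sc$truth$section_area_px - 1), 0.02)

  expect_error(segment_section(section_image(matrix(0L, 20, 20), 13.55)),
               "empty section")
  full <- segment_section(section_image(matrix(255L, 20, 20), 13.55))
  expect_true(all(full$mask))

  # padding with background does not change the mask content
  img <- sc$image$pixels
  pad <- matrix(0L, nrow(img) + 40, ncol(img) + 40)
  pad[21:(20 + nrow(img)), 21:(20 + ncol(img))] <- img
  mp <- segment_section(section_image(pad, sc$image$resolution))
  expect_equal(sum(mp$mask), sum(mask$mask))
  expect_identical(mp$mask[21:(20 + nrow(img)), 21:(20 + ncol(img))],
                   mask$mask)
})

test_that("detect_bundles finds exactly the planted bundles", {
  sc <- small_scene(seed = 5)
  mask <- segment_section(sc$image)
  det <- detect_bundles(sc$image, mask)
  expect_equal(nrow(det$regions), nrow(sc$truth$bundles))
  expect_equal(nrow(det$rejects), 0)
  n_match <- match_centroids(
    as.matrix(sc$truth$bundles[, c("x_px", "y_px")]),
    as.matrix(det$regions[, c("x_px", "y_px")]), tol_px = 1)
  expect_equal(n_match, nrow(sc$truth$bundles))
  # regions pairwise disjoint
  all_px <- do.call(rbind, det$pixels)
  expect_equal(nrow(all_px), nrow(unique(all_px)))
  expect_error(detect_bundles(sc$image, mask, min_area = 1, max_area = 0.5),
               "min_area")
})

test_that("area and solidity filters reject invalid candidates", {
  sc <- small_scene(seed = 6)
  mask <- segment_section(sc$image)
  # min_area above the smallest planted bundle removes it from regions
  det <- detect_bundles(sc$image, mask)
  amin <- min(det$regions$area_mm2)
  det2 <- detect_bundles(sc$image, mask, min_area = amin * 1.01)
  expect_equal(nrow(det2$regions), nrow(det$regions) - 1)
  expect_true("below_min_area" %in% det2$rejects$reason)

  # two bundles fused into one blob exceed max_area and land in rejects
  res <- 27.1
  img <- matrix(0L, 200, 200)
  xc <- ((1:200) - 0.5) * res / 1000; yc <- xc
  X <- matrix(xc, 200, 200); Y <- matrix(yc, 200, 200, byrow = TRUE)
  tissue <- (X - 2.7)^2 + (Y - 2.7)^2 <= 2.5^2
  img[tissue] <- 120L
  fused <- ((X - 2.5)^2 + (Y - 2.7)^2 <= 0.4^2) |
    ((X - 3.0)^2 + (Y - 2.7)^2 <= 0.4^2)
  img[fused & tissue] <- 220L
  si <- section_image(img, res)
  m <- segment_section(si)
  d <- detect_bundles(si, m, min_area = 0.005, max_area = 0.5)
  expect_equal(nrow(d$regions), 0)
  expect_equal(d$rejects$reason, "above_max_area")

  # a thin cross fails the solidity filter
  img2 <- matrix(0L, 120, 120)
  img2[20:100, 20:100] <- 120L
  img2[58:62, 30:90] <- 220L
  img2[30:90, 58:62] <- 220L
  si2 <- section_image(img2, res)
  d2 <- detect_bundles(si2, segment_section(si2), min_area = 0.005,
                       max_area = 2, min_solidity = 0.5)
  expect_equal(nrow(d2$regions), 0)
  expect_equal(d2$rejects$reason, "low_solidity")
})

test_that("zone partition is exact and fixed_depth places the boundary", {
  sc <- small_scene(seed = 7)
  mask <- segment_section(sc$image)
  det <- detect_bundles(sc$image, mask)
  part <- partition_zones(mask, det)
  # partition law: EZ + PZ + IZ = mask, exactly
  expect_equal(sum(part$labels > 0), sum(mask$mask))
  expect_true(all((part$labels > 0) == mask$mask))
  expect_equal(sum(part$labels == 1) + sum(part$labels == 2) +
                 sum(part$labels == 3), sum(mask$mask))

  # fixed_depth: boundary exactly at the requested distance-transform level
  pf <- partition_zones(mask, det, pz_policy = list(fixed_depth = 1.2))
  expect_equal(pf$pz_depth_mm, 1.2)
  D <- shankvb:::depth_map_mm(mask$mask, mask$resolution)
  expect_true(all(D[pf$labels == 3] > 1.2))
  expect_true(all(D[pf$labels == 2] <= 1.2))
  # fixed_depth is idempotent and independent of the bundle input
  pf2 <- partition_zones(mask, NULL, pz_policy = list(fixed_depth = 1.2))
  expect_identical(pf$labels, pf2$labels)

  expect_error(partition_zones(mask, det, ez_thickness = 10),
               "inradius")
})

test_that("density-valley boundary lands within a bundle diameter of truth", {
  sc <- small_scene(seed = 8)
  mask <- segment_section(sc$image)
  det <- detect_bundles(sc$image, mask)
  part <- partition_zones(mask, det)
  mean_diam <- 2 * sqrt(mean(det$regions$area_mm2) / pi)
  expect_lt(abs(part$pz_depth_mm - sc$truth$pz_depth_mm), mean_diam)
})

test_that("a constructed valley in centroid depths is detected", {
  # bimodal depth profile: dense shallow band, gap, deep cluster
  depths <- c(runif(60, 0.2, 1.0), runif(40, 2.0, 3.0))
  d <- shankvb:::density_valley_depth(depths, bw = 0.25, inradius = 4)
  expect_gt(d, 1.0)
  expect_lt(d, 2.2)
  # monotone decline has no valley
  expect_true(is.na(shankvb:::density_valley_depth(
    c(runif(50, 0.2, 1.0), runif(20, 1.0, 4.0) * 0.9), bw = 0.25,
    inradius = 4)))
})

test_that("assign_zone follows the centroid rule and is exhaustive", {
  sc <- small_scene(seed = 9)
  ph <- phenotype_section(sc$image)
  reg <- ph$bundles$regions
  expect_true(all(reg$zone %in% c("PZ", "IZ")))
  expect_equal(sum(reg$zone == "PZ") + sum(reg$zone == "IZ"), nrow(reg))
  # zone labels at the centroid pixel match the assignment (EZ -> PZ)
  lab <- ph$partition$labels[cbind(ceiling(reg$x_px), ceiling(reg$y_px))]
  expect_true(all(reg$zone == c("PZ", "PZ", "IZ")[lab]))
  # a centroid outside the section errors
  fake <- ph$bundles
  fake$regions$x_px[1] <- 1.5; fake$regions$y_px[1] <- 1.5
  expect_error(assign_zone(fake, ph$partition), "outside")
})

test_that("recovered zone assignment matches the planted zones", {
  sc <- small_scene(seed = 10)
  mask <- segment_section(sc$image)
  det <- detect_bundles(sc$image, mask)
  part <- partition_zones(mask, det,
                          pz_policy = list(fixed_depth = sc$truth$pz_depth_mm))
  det <- assign_zone(det, part)
  # match detected regions to truth records by centroid and compare zones
  tr <- sc$truth$bundles
  for (i in seq_len(nrow(det$regions))) {
    j <- which.min((tr$x_px - det$regions$x_px[i])^2 +
                     (tr$y_px - det$regions$y_px[i])^2)
    expect_equal(det$regions$zone[i], tr$zone[j])
  }
})
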