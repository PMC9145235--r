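# The 36-trait registry and trait computation against generator truth.

test_that("the registry holds 36 traits in the five categories", {
  reg <- trait_registry()
  expect_equal(nrow(reg), 36)
  expect_equal(anyDuplicated(reg$trait), 0)
  counts <- table(reg$category)
  expect_equal(unname(counts[["cross_section"]]), 7)
  expect_equal(unname(counts[["epidermis_zone"]]), 2)
  expect_equal(unname(counts[["periphery_zone"]]), 7)
  expect_equal(unname(counts[["inner_zone"]]), 7)
  expect_equal(unname(counts[["vascular_bundle"]]), 13)
  expect_true(all(nzchar(reg$unit)))
})

test_that("zone thickness recovers planted band depths", {
  # perfect synthetic partition: annuli of known widths on a disk
  n <- 400L; res <- 27.1
  xc <- ((1:n) - 0.5) * res / 1000
  X <- matrix(xc, n, n); Y <- matrix(xc, n, n, byrow = TRUE)
  R <- sqrt((X - 5.42)^2 + (Y - 5.42)^2)
  lab <- matrix(0L, n, n)
  lab[R <= 5.0] <- 3L                     # IZ of radius 5 mm
  lab[R > 5.0 & R <= 5.3] <- 2L           # PZ band 0.3 mm
  lab[R > 5.3 & R <= 5.38] <- 1L          # EZ band 0.08 mm
  part <- structure(list(labels = lab, ez_depth_mm = 0.08,
                         pz_depth_mm = 0.38, policy = "synthetic",
                         centroid_px = c(n / 2, n / 2), resolution = res),
                    class = "zone_partition")
  px_w <- res / 1000
  expect_lt(abs(zone_thickness(part, "EZ") - 0.08), px_w)
  expect_lt(abs(zone_thickness(part, "PZ") - 0.3), px_w)
  expect_lt(abs(zone_thickness(part, "IZ") - 5.0), px_w)
})

test_that("EZ and PZ band widths add up under a fixed-depth partition", {
  sc <- small_scene(seed = 12)
  mask <- segment_section(sc$image)
  part <- partition_zones(mask, NULL, ez_thickness = 0.1,
                          pz_policy = list(fixed_depth = 1.0))
  ez <- zone_thickness(part, "EZ")
  pz <- zone_thickness(part, "PZ")
  expect_lt(abs(ez + pz - 1.0), 2 * mask$resolution / 1000)
})

test_that("trait vector matches the generator truth and its identities", {
  sc <- small_scene(seed = 13)
  ph <- phenotype_section(sc$image)
  tv <- ph$traits
  expect_equal(names(tv), trait_names())
  expect_equal(unname(tv["VB_N"]), nrow(sc$truth$bundles))
  expect_equal(unname(tv["PZ_VB_N"]), sum(sc$truth$bundles$zone == "PZ"))
  expect_equal(unname(tv["IZ_VB_N"]), sum(sc$truth$bundles$zone == "IZ"))
  # conservation identities, exact
  expect_equal(unname(tv["VB_N"]), unname(tv["PZ_VB_N"] + tv["IZ_VB_N"]))
  expect_equal(unname(tv["VB_A"]), unname(tv["PZ_VB_A"] + tv["IZ_VB_A"]),
               tolerance = 1e-12)
  expect_equal(unname(tv["VB_D"] * tv["SZ_A"]), unname(tv["VB_N"]),
               tolerance = 1e-9)
  expect_equal(unname(tv["PZ_VB_D"] * tv["PZ_A"]), unname(tv["PZ_VB_N"]),
               tolerance = 1e-9)
  # section area close to the analytic disk
  expect_lt(abs(tv["SZ_A"] / (pi * 9) - 1), 0.02)
  expect_gte(tv["SZ_CCA"], tv["SZ_CA"])
  expect_gte(tv["SZ_CA"], tv["SZ_A"] - 1e-12)
  expect_true(all(tv[c("PZ_VB_CAR", "IZ_VB_CAR", "VB_CAR")] > 0 &
                    tv[c("PZ_VB_CAR", "IZ_VB_CAR", "VB_CAR")] <= 1))
  expect_gte(tv["VB_LWR"], 1)
})

test_that("ARIVB is 1 for equal PZ/IZ bundle sizes and tracks size contrast", {
  eq <- generate_cross_section(
    small_shape(), bundle_spec(pz_count = 10, iz_count = 12,
                               pz_radius_mm = c(0.15, 0),
                               iz_radius_mm = c(0.15, 0),
                               min_gap_mm = 0.5), seed = 14)
  ph <- phenotype_section(eq$image)
  expect_lt(abs(ph$traits["ARIVB"] - 1), 0.05)
  # default spec: inner bundles larger, so ARIVB < 1
  sc <- small_scene(seed = 14)
  ph2 <- phenotype_section(sc$image)
  expect_lt(unname(ph2$traits["ARIVB"]), 1)
})

test_that("90-degree rotation leaves counts intact and areas near-identical", {
  sc <- small_scene(seed = 15)
  ph <- phenotype_section(sc$image)
  rot <- section_image(t(sc$image$pixels)[ncol(sc$image$pixels):1, ],
                       sc$image$resolution)
  phr <- phenotype_section(rot)
  expect_equal(unname(phr$traits["VB_N"]), unname(ph$traits["VB_N"]))
  expect_equal(unname(phr$traits["PZ_VB_N"]), unname(ph$traits["PZ_VB_N"]))
  for (tr in c("SZ_A", "SZ_CA", "SZ_CCA", "PZ_A", "IZ_A", "VB_A")) {
    expect_lt(abs(phr$traits[tr] / ph$traits[tr] - 1), 0.005, label = tr)
  }
})

test_that("adding a bundle strictly increases count, area and density", {
  a <- small_scene(seed = 16, pz = 10, iz = 12)
  b <- small_scene(seed = 16, pz = 10, iz = 13)
  pa <- phenotype_section(a$image)
  pb <- phenotype_section(b$image)
  expect_gt(pb$traits["VB_N"], pa$traits["VB_N"])
  expect_gt(pb$traits["VB_A"], pa$traits["VB_A"])
  expect_gt(pb$traits["VB_D"], pa$traits["VB_D"])
})
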