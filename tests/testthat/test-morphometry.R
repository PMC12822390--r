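test_that("moment-equivalent ellipse axes reproduce known geometries", {
  disk <- raster_disk(64, 15)
  s <- nucleus_shapes(disk)
  expect_equal(nrow(s), 1)
  expect_lt(abs(s$aspect_ratio - 1), 0.02)

  ell <- raster_ellipse_img(101, 20, 10)
  s2 <- nucleus_shapes(ell)
  expect_lt(abs(s2$aspect_ratio - 2), 0.05)

  # rotation invariance (rasterization at this size costs a few percent)
  ell_rot <- raster_ellipse_img(101, 20, 10, theta = 37 * pi / 180)
  s3 <- nucleus_shapes(ell_rot)
  expect_lt(abs(s3$aspect_ratio - s2$aspect_ratio), 0.1)

  # translation and uniform-scale invariance
  big <- raster_ellipse_img(201, 40, 20)
  s4 <- nucleus_shapes(big)
  expect_lt(abs(s4$aspect_ratio - s2$aspect_ratio), 0.02 * s2$aspect_ratio)

  shifted <- matrix(0L, 151, 151)
  shifted[30:130, 20:120] <- ell
  s5 <- nucleus_shapes(shifted)
  expect_equal(s5$aspect_ratio, s2$aspect_ratio)

  expect_error(nucleus_shapes(matrix(0L, 10, 10)), "no objects")
})

test_that("small and degenerate objects are dropped and counted", {
  img <- raster_disk(64, 15)
  img[1, 1:3] <- 2L  # collinear 3-pixel object
  s <- nucleus_shapes(img, min_area = 20)
  expect_equal(s$label, 1)
  expect_equal(attr(s, "n_dropped_small") + attr(s, "n_dropped_degenerate"),
               1)
})

test_that("zone classification follows the boundary-distance band", {
  mask <- raster_disk(221, 100)
  shapes <- data.frame(label = 1:3,
                       cx = c(111, 111 + 99, 111 + 75),
                       cy = c(111, 111, 111),
                       major_axis = c(10, 10, 10))
  # centroids sit 0, 1 and 25 pixels inside the boundary
  out <- classify_zone(shapes, mask, band = 30)
  expect_equal(out$zone, c("center", "periphery", "periphery"))
  out2 <- classify_zone(shapes, mask, band = 20)
  expect_equal(out2$zone, c("center", "periphery", "center"))

  bad <- data.frame(label = 9, cx = 1, cy = 1, major_axis = 10)
  expect_error(classify_zone(bad, mask, band = 10), "outside")
})

test_that("generated nuclei recover their zone-dependent aspect ratios", {
  ni <- make_nuclei_image(n = 150, zone_effect = 0.4, seed = 3)
  sh <- classify_zone(nucleus_shapes(ni$labels), ni$mask, band = ni$band)
  m <- merge(sh, ni$truth, by = "label")
  expect_gte(mean(m$zone == m$zone_true), 0.95)
  d_ar <- mean(m$aspect_ratio[m$zone == "periphery"]) -
    mean(m$aspect_ratio[m$zone == "center"])
  expect_lt(abs(d_ar - 0.4), 0.1)

  # null case: no zone effect
  ni0 <- make_nuclei_image(n = 150, zone_effect = 0, seed = 5)
  sh0 <- classify_zone(nucleus_shapes(ni0$labels), ni0$mask,
                       band = ni0$band)
  d0 <- mean(sh0$aspect_ratio[sh0$zone == "periphery"]) -
    mean(sh0$aspect_ratio[sh0$zone == "center"])
  expect_lt(abs(d0), 0.06)
})

test_that("marker-positive fractions respect the normalized threshold", {
  sh <- data.frame(mean_intensity = c(90, 95, 100, 105))
  ctrl <- rnorm(50, 100, 10)
  set.seed(1)
  low <- positive_fraction(sh, ctrl)
  expect_equal(low$fraction, 0)
  high <- positive_fraction(
    data.frame(mean_intensity = rep(500, 4)), ctrl)
  expect_equal(high$fraction, 1)
  expect_error(positive_fraction(sh, numeric(0)), "empty control")

  # two-population mixture recovers the positive weight
  mk <- make_marker_intensities(n = 200, frac_positive = 0.3,
                                shift_sd = 5, seed = 5)
  pf <- positive_fraction(data.frame(mean_intensity = mk$intensities),
                          mk$control_intensities)
  expect_lt(abs(pf$fraction - 0.30), 0.05)

  # invariance under global multiplicative rescaling
  pf2 <- positive_fraction(
    data.frame(mean_intensity = mk$intensities * 13),
    mk$control_intensities * 13)
  expect_equal(pf2$fraction, pf$fraction)
})

test_that("invasion ratio matches analytic areas and is resolution invariant", {
  core <- raster_disk(201, 40)
  tot <- raster_disk(201, 80)
  ir <- invasion_ratio(core, tot)
  expect_lt(abs(ir$ratio - 3), 0.02)

  # same geometry at double resolution
  ir2 <- invasion_ratio(raster_disk(401, 80), raster_disk(401, 160))
  expect_lt(abs(ir2$ratio / ir$ratio - 1), 0.01)

  # no invasion
  expect_equal(invasion_ratio(core, core)$ratio, 0)
  expect_error(invasion_ratio(matrix(0L, 10, 10), tot[1:10, 1:10]),
               "empty core")

  gen <- make_invasion_masks(core_radius = 60, spread = 40,
                             n_protrusions = 6, seed = 2)
  irg <- invasion_ratio(gen$core, gen$total)
  expect_lt(abs(sum(gen$core) / gen$truth$core_area - 1), 0.02)
  expect_lt(abs(irg$ratio / gen$truth$ratio - 1), 0.05)
  flat <- make_invasion_masks(spread = 0, seed = 2)
  expect_equal(invasion_ratio(flat$core, flat$total)$ratio, 0)
})

test_that("region mean intensity subtracts scalar or image backgrounds", {
  img <- matrix(100, 32, 32)
  mask <- raster_disk(32, 10)
  expect_equal(region_mean_intensity(img, mask, 10), 90)
  expect_equal(region_mean_intensity(img, mask, img), 0)
  expect_error(region_mean_intensity(img, matrix(0L, 32, 32)), "empty")

  dx <- make_dextran_image(level = 100, background = 10, seed = 4)
  rec <- region_mean_intensity(dx$image, dx$mask, dx$truth$background)
  expect_lt(abs(rec / dx$truth$level - 1), 0.02)
})
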