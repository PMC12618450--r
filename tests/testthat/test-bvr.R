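solid_image <- function(n, hu = 500, nd = 2, h = 0.25) {
  dims <- rep(n, nd)
  hu_image(array(hu, dim = dims), h)
}

test_that("hollow-cylinder ROI voxelises its analytic volume", {
  h <- 0.25
  img <- solid_image(80, nd = 3, h = h)   # 20 mm cube
  ring <- hollow_cylinder_mask(img, center = c(10, 10), inner_radius = 4,
                               thickness = 2, height = 10)
  v_analytic <- pi * (6^2 - 4^2) * 10
  shell <- (2 * pi * 4 * 10 + 2 * pi * 6 * 10 + 2 * pi * 20) * h
  expect_lt(abs(ring$v0 - v_analytic), shell)
  expect_error(hollow_cylinder_mask(img, c(10, 10), thickness = 0),
               "thickness")
  # a cylinder inside solid bone gives ratio 1
  expect_equal(bone_volume_ratio(img, ring)$ratio, 1)
})

test_that("equal-volume sphere matches the closed-form radius", {
  img <- solid_image(80, nd = 3)
  v0 <- pi * (6^2 - 4^2) * 10
  sph <- equal_volume_sphere_mask(img, center = rep(10, 3), v0 = v0)
  expect_equal(sph$params$radius, (3 * v0 / (4 * pi))^(1 / 3))
  # voxelised volume within a half-voxel surface shell of the target
  r <- sph$params$radius
  shell <- 4 * pi * r^2 * img$voxel_size / 2
  expect_lt(abs(sph$v0 - v0), shell)
  # one-voxel target gives a single voxel
  tiny <- equal_volume_sphere_mask(img, center = c(10.125, 10.125, 10.125),
                                   v0 = img$voxel_size^3)
  expect_equal(sum(tiny$mask), 1L)
  # a large sphere at the corner does not fit
  expect_error(equal_volume_sphere_mask(img, center = c(0.5, 0.5, 0.5),
                                        v0 = v0), "fit")
})

test_that("BVR thresholding counts the bone band and bounds the ratio", {
  img <- generate_trabecular_image(c(96, 96), target_bvr = 0.47, seed = 13)
  # local ROI fluctuation scales with the correlation area: a 300 mm^2
  # disc holds ~800 independent patches, so +-0.06 is ~3 sigma
  disc <- equal_volume_sphere_mask(img, center = c(12, 12), v0 = 300)
  r <- bone_volume_ratio(img, disc)
  expect_gte(r$ratio, 0); expect_lte(r$ratio, 1)
  expect_lt(abs(r$ratio - 0.47), 0.06)
  # all-background and all-bone ROIs hit the extremes
  bg <- solid_image(16, hu = 0)
  m <- equal_volume_sphere_mask(bg, center = c(2, 2), v0 = 3)
  expect_equal(bone_volume_ratio(bg, m)$ratio, 0)
  expect_equal(bone_volume_ratio(solid_image(16, hu = 600), m)$ratio, 1)
  expect_error(bone_volume_ratio(img, disc, hu_band = c(500, 100)),
               "lower")
})

test_that("ROI geometry is invariant under image translation", {
  base <- generate_trabecular_image(c(64, 64), target_bvr = 0.47, seed = 8)
  shifted <- base
  shifted$origin <- base$origin + c(5, -3)
  m1 <- hollow_cylinder_mask(base, center = c(8, 8), inner_radius = 3,
                             thickness = 2)
  m2 <- hollow_cylinder_mask(shifted, center = c(8, 8) + c(5, -3),
                             inner_radius = 3, thickness = 2)
  expect_identical(m1$mask, m2$mask)
  expect_equal(bone_volume_ratio(base, m1)$ratio,
               bone_volume_ratio(shifted, m2)$ratio)
})

test_that("paired comparison reproduces the closed-form t statistic", {
  a <- c(0.7, 0.8, 0.75); b <- c(0.5, 0.45, 0.5)
  res <- paired_comparison(a, b)
  d <- a - b
  t_hand <- mean(d) / (sd(d) / sqrt(3))
  expect_equal(res$t, t_hand)
  expect_equal(res$df, 2)
  expect_equal(res$p_value, 2 * pt(-abs(t_hand), 2))
  expect_equal(res$mean_difference, mean(d))
  # identical lists: t = 0, p = 1 (degenerate zero-variance limit)
  same <- paired_comparison(a, a)
  expect_equal(same$t, 0); expect_equal(same$p_value, 1)
  expect_true(same$degenerate)
  # constant nonzero difference: p -> 0 with the degenerate flag
  shift <- paired_comparison(a + 0.1, a)
  expect_equal(shift$p_value, 0)
  expect_true(shift$degenerate)
  expect_error(paired_comparison(0.7, 0.5), "n >= 2")
  expect_error(paired_comparison(a, b[1:2]), "unequal")
})

test_that("remodeled densities project back to analysable HU images", {
  expect_equal(density_to_hu(1.041395), 0)
  expect_equal(density_to_hu(2.0), 958605 / 1017)  # = 942.5811 HU
  m <- lame_disc_model(32)
  mat <- m$mat
  mat$density[mat$remodels] <- 1.5
  proj <- density_to_hu_projection(mat, m$mesh)
  expect_equal(dim(proj$values), m$mesh$grid_dim)
  inside <- m$mesh$voxel_index[mat$remodels]
  expect_equal(unique(proj$values[inside]), density_to_hu(1.5))
  expect_equal(unique(proj$values[-inside]), 0)
  # round trip through the BVR pipeline: 1.5 g/cm^3 maps inside the band
  ring <- hollow_cylinder_mask(proj, m$center, inner_radius = 4,
                               thickness = 2)
  expect_equal(bone_volume_ratio(proj, ring)$ratio, 1)
})
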