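test_that("generator hits the target bone volume ratio and is seeded", {
  img <- generate_trabecular_image(c(96, 96), target_bvr = 0.47, seed = 3)
  bvr <- mean(img$values >= 200 & img$values <= 1000)
  expect_lt(abs(bvr - 0.47), 0.02)
  # identical seed gives bit-identical grids; different seed differs
  img2 <- generate_trabecular_image(c(96, 96), target_bvr = 0.47, seed = 3)
  expect_identical(img$values, img2$values)
  img3 <- generate_trabecular_image(c(96, 96), target_bvr = 0.47, seed = 4)
  expect_false(identical(img$values, img3$values))
  # the generator leaves the caller's RNG stream untouched
  set.seed(11); before <- rnorm(1)
  set.seed(11); invisible(generate_trabecular_image(c(16, 16), seed = 5))
  expect_identical(rnorm(1), before)
})

test_that("degenerate and invalid generator inputs behave", {
  all_bone <- generate_trabecular_image(c(12, 12), target_bvr = 1, seed = 1)
  expect_true(all(all_bone$values >= 200 & all_bone$values <= 1000))
  expect_error(generate_trabecular_image(c(0, 4), seed = 1), "shape")
  expect_error(generate_trabecular_image(c(8, 8), target_bvr = 1.4, seed = 1),
               "target_bvr")
  expect_error(generate_trabecular_image(c(8, 8), correlation_length = 0.1,
                                         voxel_size = 0.25, seed = 1))
})

test_that("realized BVR error shrinks with grid size", {
  err <- sapply(c(24, 96), function(n) {
    img <- generate_trabecular_image(c(n, n), target_bvr = 0.47, seed = 7)
    abs(mean(img$values >= 200) - 0.47)
  })
  expect_lte(err[2], err[1] + 1e-3)
  expect_lt(err[2], 0.02)
})

test_that("3D generation works and bone HU ramps with depth from the void", {
  img <- generate_trabecular_image(c(32, 32, 32), target_bvr = 0.47, seed = 2)
  bone <- img$values >= 200
  expect_lt(abs(mean(bone) - 0.47), 0.02)
  expect_true(all(img$values[!bone] == 0))
  # strut cores (away from the surface) read denser than strut surfaces
  expect_gt(max(img$values[bone]), min(img$values[bone]))
})

test_that("drilling voxelises the defect cylinder to within one voxel shell", {
  h <- 0.5
  img <- generate_trabecular_image(c(40, 40, 40), voxel_size = h,
                                   target_bvr = 0.47, seed = 9)
  def <- defect_spec(center = c(10, 10), diameter = 8, depth = 10,
                     anchor_diameter = 0)
  out <- drill_and_insert(img, def)
  v_void <- sum(out$labels == "void") * h^3
  v_analytic <- pi * 4^2 * 10
  shell <- (2 * pi * 4 * 10 + 2 * pi * 4^2) * h   # one-voxel boundary shell
  expect_lt(abs(v_void - v_analytic), shell)
  expect_true(all(out$image$values[out$labels == "void"] == 0))
})

test_that("press-fit anchors contact bone directly and drilling is idempotent", {
  img <- generate_trabecular_image(c(40, 40), voxel_size = 0.5,
                                   target_bvr = 0.47, seed = 9)
  def <- defect_spec(center = c(10, 10), diameter = 8)  # anchor = drill
  out <- drill_and_insert(img, def)
  expect_equal(sum(out$labels == "void"), 0)
  expect_gt(sum(out$labels == "anchor"), 0)
  again <- drill_and_insert(out$image, def)
  expect_identical(out$labels, again$labels)
  expect_identical(out$image$values, again$image$values)
  # defect outside the grid errors
  expect_error(drill_and_insert(img, defect_spec(center = c(2, 2),
                                                 diameter = 8)), "outside")
  expect_error(defect_spec(center = c(10, 10), diameter = 8,
                           anchor_diameter = 9))
})

test_that("HU images round-trip through TIFF plus sidecar", {
  img <- generate_trabecular_image(c(24, 24, 8), target_bvr = 0.4, seed = 6)
  path <- tempfile(fileext = ".tif")
  write_hu_tiff(img, path)
  back <- read_hu_tiff(path)
  tol <- diff(range(img$values)) / 65535 * 1.01   # 16-bit quantisation
  expect_lt(max(abs(back$values - img$values)), tol)
  expect_equal(back$voxel_size, img$voxel_size)
  expect_equal(back$hu_bone, img$hu_bone)
  expect_equal(dim(back$values), dim(img$values))
  hist <- hu_histogram(img)
  expect_equal(sum(hist$count), length(img$values))
  unlink(c(path, paste0(path, ".yml")))
})
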