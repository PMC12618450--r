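test_that("a free body under uniform eigenstrain is stress- and energy-free", {
  # 2D plane stress and 3D: strain equals the eigenstrain, stress vanishes
  for (nd in c(2, 3)) {
    labels <- if (nd == 2) matrix("bone", 3, 3) else array("bone", c(3, 3, 3))
    mesh <- voxel_mesh(labels, 1, region_map = c(bone = "bone"))
    mat <- single_element_material(mesh, E = 4000, nu = 0.3)
    st <- solve_hygroelastic(mesh, mat, 0.01, bc_free_swelling(mesh))
    ncomp_n <- if (nd == 2) 2 else 3
    expect_equal(max(abs(st$stress)), 0, tolerance = 1e-10)
    expect_equal(max(abs(st$sed)), 0, tolerance = 1e-12)
    expect_equal(st$strain[, seq_len(ncomp_n)],
                 matrix(0.01, nrow(mesh$elem), ncomp_n),
                 tolerance = 1e-10)
  }
})

test_that("clamped-element constrained swelling matches the closed form", {
  # plane strain, fully clamped: sigma_xx = sigma_yy = -E e0 / (1 - 2 nu)
  mesh <- single_element_mesh(2)
  mat <- single_element_material(mesh, E = 1000, nu = 0.3)
  st <- solve_hygroelastic(mesh, mat, 0.01, bc_clamp_all(mesh),
                           mode = "plane_strain")
  expect_equal(st$stress[1, 1:2], rep(-1000 * 0.01 / (1 - 2 * 0.3), 2))
  expect_equal(st$stress[1, 3], 0)
  # independent single-element assembly oracle: K u = f with u = 0
  # everywhere means stress = -D * eps_hs exactly; checked above via the
  # analytic reduction.  3D clamped cube: sigma = -E e0/(1-2nu) too.
  mesh3 <- single_element_mesh(3)
  mat3 <- single_element_material(mesh3, E = 1000, nu = 0.3)
  st3 <- solve_hygroelastic(mesh3, mat3, 0.01, bc_clamp_all(mesh3))
  expect_equal(st3$stress[1, 1:3], rep(-1000 * 0.01 / (1 - 2 * 0.3), 3))
})

test_that("rigid translation produces no strain energy", {
  blk <- block_model(n = 4)
  bd <- which(apply(blk$mesh$nodes, 1, function(p) {
    any(p %in% range(blk$mesh$nodes[, 1]))
  }))
  fixed <- sort(as.vector(outer(1:2, (bd - 1L) * 2L, `+`)))
  bc <- boundary_conditions(fixed, values = rep(c(0.3, -0.1),
                                                length(fixed) / 2),
                            tag = "rigid")
  st <- solve_hygroelastic(blk$mesh, blk$mat, 0, bc)
  expect_lt(max(abs(st$sed)), 1e-20)
  expect_lt(max(abs(st$strain)), 1e-12)
})

test_that("insufficient constraints are reported as a singular system", {
  mesh <- single_element_mesh(2)
  mat <- single_element_material(mesh)
  bc <- boundary_conditions(1L, tag = "underconstrained")
  expect_error(solve_hygroelastic(mesh, mat, 0.01, bc), "rigid-body")
  expect_no_error(solve_hygroelastic(mesh, single_element_material(mesh),
                                     0.01, bc_clamp_all(mesh)))
  bad <- mat; bad$modulus[1] <- -5
  expect_error(solve_hygroelastic(mesh, bad, 0.01, bc_clamp_all(mesh)),
               "modulus")
})

test_that("element strain energy density contracts stress with elastic strain", {
  expect_equal(element_sed(matrix(0, 2, 2), matrix(0, 2, 2)), 0)
  # uniaxial: U = 1/2 * 2 MPa * 0.001
  expect_equal(element_sed(diag(c(2, 0)), diag(c(0.001, 0))), 0.001)
  # pure tensor shear counts both symmetric components
  sig <- matrix(c(0, 1, 1, 0), 2, 2)
  eps <- matrix(c(0, 5e-4, 5e-4, 0), 2, 2)
  expect_equal(element_sed(sig, eps), 5e-4)
  # Voigt vectors with engineering shear agree with the tensor form
  expect_equal(element_sed(c(0, 0, 1), c(0, 0, 1e-3)), 5e-4)
})

test_that("stimulus field divides energy by density and guards the floor", {
  mesh <- single_element_mesh(2)
  mat <- single_element_material(mesh, rho = 1.1)
  st <- solve_hygroelastic(mesh, mat, 0.01, bc_clamp_all(mesh))
  st$sed[1] <- 0.0044
  expect_equal(stimulus_field(st, mat)[1], 0.004)
  st$sed[1] <- 0
  expect_equal(stimulus_field(st, mat)[1], 0)
  st$sed[1] <- 0.02
  mat$density[1] <- 0.01
  expect_equal(stimulus_field(st, mat)[1], 2.0)
  mat$density[1] <- 0.001
  expect_error(stimulus_field(st, mat), "corrupted")
})

test_that("shrink-fit oracle limits behave", {
  expect_equal(lame_shrinkfit_oracle(4, 8, 2500, 0.3, 2500, 0.3, 0), 0)
  # a stiffer, larger annulus resists more: p grows towards the b -> Inf
  # limit
  p10 <- lame_shrinkfit_oracle(1, 10, 2500, 0.3, 6000, 0.3, 0.05)
  p100 <- lame_shrinkfit_oracle(1, 100, 2500, 0.3, 6000, 0.3, 0.05)
  expect_lt(p10, p100)
  expect_error(lame_shrinkfit_oracle(8, 4, 2500, 0.3, 6000, 0.3, 0.05))
})

test_that("voxelised two-material disc reproduces the shrink-fit pressure", {
  m <- lame_disc_model(96)
  st <- solve_hygroelastic(m$mesh, m$mat, m$eig0, m$bc,
                           mode = "plane_stress")
  fac <- interface_facets(m$mesh, axis_center = m$center)
  p <- interface_normal_pressure(st, m$mesh, fac)
  expect_lt(abs(mean(p) / m$oracle - 1), 0.05)
  # single-side estimates bracket the two-side mean on the staircase
  pb <- interface_normal_pressure(st, m$mesh, fac, side = "bone")
  pa <- interface_normal_pressure(st, m$mesh, fac, side = "anchor")
  expect_lt(mean(pb), mean(p))
  expect_gt(mean(pa), mean(p))
})

test_that("refining the mesh changes the interface pressure by under 5%", {
  p_of <- function(n) {
    m <- lame_disc_model(n)
    st <- solve_hygroelastic(m$mesh, m$mat, m$eig0, m$bc,
                             mode = "plane_stress")
    mean(interface_normal_pressure(st, m$mesh,
                                   interface_facets(m$mesh, m$center)))
  }
  p1 <- p_of(64); p2 <- p_of(128)
  expect_lt(abs(p2 - p1) / p2, 0.05)
})

test_that("mesh construction indexes nodes and volumes consistently", {
  labels <- matrix("outside", 4, 4)
  labels[2:3, 2:3] <- "bone"
  mesh <- voxel_mesh(labels, 0.5, origin = c(1, 2),
                     region_map = c(bone = "bone"))
  expect_equal(nrow(mesh$elem), 4L)
  expect_equal(nrow(mesh$nodes), 9L)
  expect_equal(mesh$element_volume, 0.25)
  expect_equal(mesh$centroid[1, ], c(1 + 0.75, 2 + 0.75))
  expect_error(voxel_mesh(matrix("void", 2, 2), 0.5), "no active")
})
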