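# shared fixture builders, all constructed in code at test time

# two-material disc: swelling core (radius a) inside a bone annulus
# (outer radius b), voxelised on an n x n grid, free outer boundary
lame_disc_model <- function(n, a = 4, b = 8, e_inner = 2500, e_outer = 6000,
                            nu = 0.3, e0 = 0.05) {
  h <- 2 * b / n
  cc <- (seq_len(n) - 0.5) * h
  r <- sqrt(outer((cc - b)^2, (cc - b)^2, `+`))
  labels <- matrix("outside", n, n)
  labels[r < b] <- "bone"
  labels[r < a] <- "anchor"
  mesh <- voxel_mesh(labels, h)
  anchor <- mesh$region == "anchor"
  mat <- material_state(density = ifelse(anchor, NA, 1),
                        modulus = ifelse(anchor, e_inner, e_outer),
                        poisson = nu, remodels = !anchor)
  list(mesh = mesh, mat = mat, eig0 = ifelse(anchor, e0, 0),
       bc = bc_free_swelling(mesh), center = c(b, b),
       oracle = lame_shrinkfit_oracle(a, b, e_inner, nu, e_outer, nu, e0))
}

# single-element mesh (2D if nd == 2, 3D if nd == 3), edge h
single_element_mesh <- function(nd = 2, h = 1) {
  labels <- if (nd == 2) matrix("bone", 1, 1) else array("bone", c(1, 1, 1))
  voxel_mesh(labels, h, region_map = c(bone = "bone"))
}

single_element_material <- function(mesh, E = 1000, nu = 0.3, rho = 1) {
  n <- nrow(mesh$elem)
  material_state(rep(rho, n), rep(E, n), nu, rep(TRUE, n))
}

# fully clamp every node of a mesh
bc_clamp_all <- function(mesh) {
  boundary_conditions(seq_len(nrow(mesh$nodes) * mesh$nd), tag = "clamped")
}

# small uniform bone block for coupled remodeling tests
block_model <- function(n = 4, h = 0.5, rho = 1.0, nu = 0.3) {
  labels <- matrix("bone", n, n)
  mesh <- voxel_mesh(labels, h, region_map = c(bone = "bone"))
  ne <- nrow(mesh$elem)
  mat <- material_state(rep(rho, ne), rep(density_to_modulus(rho), ne), nu)
  lo <- range(mesh$nodes[, 1])
  bc <- bc_fix_where(mesh, function(p) {
    p[, 1] %in% lo | p[, 2] %in% range(p[, 2])
  }, tag = "constrained_lateral")
  list(mesh = mesh, mat = mat, bc = bc)
}
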