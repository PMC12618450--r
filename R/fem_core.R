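#' Voxel finite element mesh
#'
#' Builds a regular mesh of 4-node quadrilaterals (2D) or 8-node hexahedra
#' (3D) from a labeled voxel grid: one element per active voxel.  The
#' bone--anchor interface is tied (shared nodes); swelling keeps it in
#' compression, so a tied interface transfers normal pressure like closed
#' frictional contact, and friction enters only the push-out estimate.
#'
#' @param labels Character array of voxel labels (2D or 3D).
#' @param voxel_size Element edge length, mm.
#' @param origin Physical coordinate of the grid corner, mm.
#' @param region_map Named character vector mapping voxel labels to mesh
#'   regions (\code{"bone"}, \code{"marrow"} or \code{"anchor"}); unmapped
#'   labels are excluded from the mesh and carry no stiffness.  The
#'   default meshes the pore space as soft remodelable marrow, so the
#'   domain stays connected while load concentrates in the struts.
#' @return An object of class \code{"voxel_mesh"}: node coordinates (mm),
#'   element connectivity, per-element region and centroid, element volume
#'   (mm^3, unit thickness in 2D), and the linear voxel index each element
#'   came from.
#' @export
voxel_mesh <- function(labels, voxel_size,
                       origin = rep(0, length(dim(labels))),
                       region_map = c(bone = "bone", marrow = "marrow",
                                      anchor = "anchor")) {
  d <- dim(labels)
  nd <- length(d)
  stopifnot(nd %in% c(2L, 3L), voxel_size > 0)
  keep <- which(labels %in% names(region_map))
  if (length(keep) == 0) stop("no active elements under region_map")
  region <- unname(region_map[labels[keep]])
  vox <- arrayInd(keep, d) - 1L               # 0-based voxel indices
  nn_grid <- d + 1L
  offs <- corner_offsets(nd)
  nne <- nrow(offs)
  grid_node_id <- function(ix) {
    id <- ix[, 1]
    mult <- 1
    for (a in 2:nd) {
      mult <- mult * nn_grid[a - 1]
      id <- id + ix[, a] * mult
    }
    id + 1L
  }
  conn_grid <- matrix(0L, nrow = length(keep), ncol = nne)
  for (c_i in seq_len(nne)) {
    ix <- sweep(vox, 2, offs[c_i, ], `+`)
    conn_grid[, c_i] <- grid_node_id(ix)
  }
  used <- sort(unique(as.vector(conn_grid)))
  remap <- integer(prod(nn_grid))
  remap[used] <- seq_along(used)
  conn <- matrix(remap[conn_grid], nrow = nrow(conn_grid))
  node_ix <- arrayInd(used, nn_grid) - 1L
  nodes <- sweep(node_ix * voxel_size, 2, origin, `+`)
  centroid <- sweep((vox + 0.5) * voxel_size, 2, origin, `+`)
  mesh <- structure(list(
    nd = nd, h = voxel_size, nodes = nodes, elem = conn,
    region = region, centroid = centroid,
    element_volume = voxel_size^nd * (if (nd == 2L) 1 else 1),
    voxel_index = keep, grid_dim = d, origin = origin,
    cache = new.env(parent = emptyenv())
  ), class = "voxel_mesh")
  mesh
}

corner_offsets <- function(nd) {
  if (nd == 2L) {
    matrix(c(0L, 0L, 1L, 0L, 1L, 1L, 0L, 1L), ncol = 2, byrow = TRUE)
  } else {
    matrix(c(0L, 0L, 0L, 1L, 0L, 0L, 1L, 1L, 0L, 0L, 1L, 0L,
             0L, 0L, 1L, 1L, 0L, 1L, 1L, 1L, 1L, 0L, 1L, 1L),
           ncol = 3, byrow = TRUE)
  }
}

#' @export
print.voxel_mesh <- function(x, ...) {
  cat("<voxel_mesh> ", x$nd, "D, ", nrow(x$elem), " elements (",
      sum(x$region == "bone"), " bone, ", sum(x$region == "marrow"),
      " marrow, ", sum(x$region == "anchor"), " anchor), ",
      nrow(x$nodes), " nodes, h = ", x$h, " mm\n", sep = "")
  invisible(x)
}

# unit-modulus constitutive matrix (Voigt, engineering shear)
dhat_matrix <- function(nu, mode) {
  switch(mode,
    plane_stress = {
      m <- matrix(c(1, nu, 0, nu, 1, 0, 0, 0, (1 - nu) / 2), 3, 3)
      m / (1 - nu^2)
    },
    plane_strain = {
      m <- matrix(c(1 - nu, nu, 0, nu, 1 - nu, 0, 0, 0, (1 - 2 * nu) / 2),
                  3, 3)
      m / ((1 + nu) * (1 - 2 * nu))
    },
    `3d` = {
      lam <- nu / ((1 + nu) * (1 - 2 * nu))
      mu <- 1 / (2 * (1 + nu))
      m <- matrix(0, 6, 6)
      m[1:3, 1:3] <- lam
      diag(m)[1:3] <- lam + 2 * mu
      diag(m)[4:6] <- mu
      m
    },
    stop("unknown mode ", mode))
}

# unit eigenstrain vector (isotropic swelling of unit linear strain)
eig_voigt_unit <- function(nu, mode) {
  switch(mode,
    plane_stress = c(1, 1, 0),
    plane_strain = c(1 + nu, 1 + nu, 0),  # standard plane-strain reduction
    `3d` = c(1, 1, 1, 0, 0, 0))
}

# shape-function derivative matrix dN/dxi at a local point (rows: nodes)
shape_grad <- function(xi, nd) {
  offs <- corner_offsets(nd) * 2L - 1L      # node signs +-1
  nne <- nrow(offs)
  g <- matrix(0, nne, nd)
  for (i in seq_len(nne)) {
    for (a in seq_len(nd)) {
      term <- offs[i, a] / 2^nd
      for (b in setdiff(seq_len(nd), a)) term <- term * (1 + offs[i, b] * xi[b])
      g[i, a] <- term
    }
  }
  g
}

# B matrix (strain-displacement) from dN/dx; Voigt order
# 2D: (xx, yy, xy); 3D: (xx, yy, zz, xy, yz, zx); engineering shear
b_matrix <- function(dndx) {
  nne <- nrow(dndx)
  nd <- ncol(dndx)
  if (nd == 2L) {
    B <- matrix(0, 3, 2 * nne)
    for (i in seq_len(nne)) {
      B[1, 2 * i - 1] <- dndx[i, 1]
      B[2, 2 * i] <- dndx[i, 2]
      B[3, 2 * i - 1] <- dndx[i, 2]
      B[3, 2 * i] <- dndx[i, 1]
    }
  } else {
    B <- matrix(0, 6, 3 * nne)
    for (i in seq_len(nne)) {
      ix <- 3 * i - 2; iy <- 3 * i - 1; iz <- 3 * i
      B[1, ix] <- dndx[i, 1]
      B[2, iy] <- dndx[i, 2]
      B[3, iz] <- dndx[i, 3]
      B[4, ix] <- dndx[i, 2]; B[4, iy] <- dndx[i, 1]
      B[5, iy] <- dndx[i, 3]; B[5, iz] <- dndx[i, 2]
      B[6, ix] <- dndx[i, 3]; B[6, iz] <- dndx[i, 1]
    }
  }
  B
}

# element integration data for a square/cube element of edge h:
# B at the 2^nd Gauss points and at the centroid, with weights * detJ
element_integration <- function(nd, h) {
  gp <- 1 / sqrt(3)
  pts <- corner_offsets(nd) * 2L - 1L
  pts <- pts * gp
  detj <- (h / 2)^nd
  Bs <- lapply(seq_len(nrow(pts)), function(i) {
    b_matrix(shape_grad(pts[i, ], nd) * (2 / h))
  })
  list(B_gauss = Bs, w = rep(detj, nrow(pts)),
       B_center = b_matrix(shape_grad(rep(0, nd), nd) * (2 / h)))
}

# unit-modulus element stiffness and unit eigenstrain load for given nu
element_matrices <- function(nd, h, nu, mode) {
  integ <- element_integration(nd, h)
  Dh <- dhat_matrix(nu, mode)
  ev <- eig_voigt_unit(nu, mode)
  ndof <- ncol(integ$B_gauss[[1]])
  Ke <- matrix(0, ndof, ndof)
  fe <- numeric(ndof)
  for (q in seq_along(integ$B_gauss)) {
    B <- integ$B_gauss[[q]]
    Ke <- Ke + crossprod(B, Dh %*% B) * integ$w[q]
    fe <- fe + crossprod(B, Dh %*% ev)[, 1] * integ$w[q]
  }
  list(Ke = Ke, fe = fe, B_center = integ$B_center, Dh = Dh, ev = ev)
}

#' Boundary conditions for a voxel mesh
#'
#' @param fixed_dofs Integer vector of constrained global degrees of
#'   freedom (dof of node n, component c is (n-1)*nd + c).
#' @param values Prescribed displacement at each fixed dof (default 0).
#' @param tag Descriptive tag (\code{"free_swelling"},
#'   \code{"constrained_lateral"}, \code{"custom"}, ...).
#' @return An object of class \code{"boundary_conditions"}.
#' @export
boundary_conditions <- function(fixed_dofs, values = 0, tag = "custom") {
  fixed_dofs <- as.integer(fixed_dofs)
  stopifnot(!anyDuplicated(fixed_dofs))
  structure(list(fixed_dofs = fixed_dofs,
                 values = rep_len(values, length(fixed_dofs)), tag = tag),
            class = "boundary_conditions")
}

#' Fix all components of nodes selected by a coordinate predicate
#'
#' @param mesh A \code{\link{voxel_mesh}}.
#' @param predicate Function of the node coordinate matrix returning a
#'   logical vector of nodes to constrain.
#' @param dofs Components to fix (default all).
#' @param tag Tag passed to \code{\link{boundary_conditions}}.
#' @return A \code{\link{boundary_conditions}} object.
#' @export
bc_fix_where <- function(mesh, predicate, dofs = seq_len(mesh$nd),
                         tag = "custom") {
  sel <- which(predicate(mesh$nodes))
  if (length(sel) == 0) stop("predicate selects no nodes")
  fixed <- as.vector(outer(dofs, (sel - 1L) * mesh$nd, `+`))
  boundary_conditions(sort(fixed), tag = tag)
}

#' Minimal rigid-body constraints for a free body
#'
#' Pins translation and rotation (3-2-1 scheme in 3D; point plus one
#' tangential component in 2D) using nodes nearest the body center, where
#' an isotropic free-swelling field has zero displacement, so the patch
#' test is unperturbed.
#'
#' @param mesh A \code{\link{voxel_mesh}}.
#' @return A \code{\link{boundary_conditions}} with tag
#'   \code{"free_swelling"}.
#' @export
bc_free_swelling <- function(mesh) {
  ctr <- colMeans(mesh$nodes)
  d2 <- rowSums(sweep(mesh$nodes, 2, ctr)^2)
  a <- which.min(d2)
  pa <- mesh$nodes[a, ]
  # companion nodes along +x (and +y in 3D) from the pinned node
  on_xaxis <- which(apply(mesh$nodes, 1, function(p) {
    all(abs(p[-1] - pa[-1]) < 1e-9) && p[1] > pa[1]
  }))
  if (length(on_xaxis) == 0) stop("degenerate mesh: no node on +x axis")
  b <- on_xaxis[which.max(mesh$nodes[on_xaxis, 1])]
  nd <- mesh$nd
  if (nd == 2L) {
    fixed <- c((a - 1L) * 2L + 1:2, (b - 1L) * 2L + 2L)
  } else {
    on_yaxis <- which(apply(mesh$nodes, 1, function(p) {
      all(abs(p[c(1, 3)] - pa[c(1, 3)]) < 1e-9) && p[2] > pa[2]
    }))
    if (length(on_yaxis) == 0) stop("degenerate mesh: no node on +y axis")
    cc <- on_yaxis[which.max(mesh$nodes[on_yaxis, 2])]
    fixed <- c((a - 1L) * 3L + 1:3, (b - 1L) * 3L + 2:3, (cc - 1L) * 3L + 3L)
  }
  boundary_conditions(sort(fixed), tag = "free_swelling")
}

#' Solve the hygro-elastic boundary value problem
#'
#' Small-strain linear elasticity with a per-element isotropic swelling
#' eigenstrain: assembles the sparse symmetric stiffness K and eigenstrain
#' load, solves K u = f by sparse Cholesky factorisation, and recovers
#' per-element centroid strain, elastic strain (total minus eigenstrain),
#' stress sigma = C (eps - eps_hs), and strain energy density
#' U = 1/2 sigma : (eps - eps_hs), which is zero under free swelling.
#'
#' @param mesh A \code{\link{voxel_mesh}}.
#' @param mat A \code{\link{material_state}} covering all elements.
#' @param eig0 Per-element scalar eigenstrain (linear swelling strain);
#'   scalars are recycled.  Typically nonzero only on anchor elements.
#' @param bc A \code{\link{boundary_conditions}} removing rigid-body modes.
#' @param mode \code{"plane_stress"} or \code{"plane_strain"} for 2D
#'   meshes; 3D meshes always use \code{"3d"}.
#' @return An object of class \code{"field_state"}: nodal displacement
#'   \code{u} (mm), per-element Voigt \code{strain}, \code{elastic_strain},
#'   \code{stress} (MPa), and \code{sed} (J/cm^3).
#' @export
solve_hygroelastic <- function(mesh, mat, eig0, bc,
                               mode = c("plane_stress", "plane_strain")) {
  nd <- mesh$nd
  mode <- if (nd == 3L) "3d" else match.arg(mode)
  nelem <- nrow(mesh$elem)
  stopifnot(length(mat$modulus) == nelem)
  if (any(mat$modulus <= 0)) stop("non-positive modulus")
  eig0 <- rep_len(eig0, nelem)
  nne <- ncol(mesh$elem)
  ndof_e <- nne * nd
  ndof <- nrow(mesh$nodes) * nd
  edof <- edof_matrix(mesh)
  # triplet indices cached on the mesh (independent of material)
  key <- "trip"
  if (is.null(mesh$cache[[key]])) {
    rix <- rep(seq_len(ndof_e), times = ndof_e)
    cix <- rep(seq_len(ndof_e), each = ndof_e)
    mesh$cache[[key]] <- list(ii = edof[, rix, drop = FALSE],
                              jj = edof[, cix, drop = FALSE])
  }
  trip <- mesh$cache[[key]]
  nus <- round(mat$poisson, 10)
  xx <- matrix(0, nelem, ndof_e * ndof_e)
  f <- numeric(ndof)
  elmat <- list()
  for (nu in unique(nus)) {
    g <- which(nus == nu)
    em <- element_matrices(nd, mesh$h, nu, mode)
    elmat[[as.character(nu)]] <- em
    xx[g, ] <- outer(mat$modulus[g], as.vector(em$Ke))
    fv <- outer(mat$modulus[g] * eig0[g], em$fe)
    f <- f + as.numeric(Matrix::sparseMatrix(
      i = as.vector(edof[g, , drop = FALSE]), j = rep(1L, length(fv)),
      x = as.vector(fv), dims = c(ndof, 1)))
  }
  K <- Matrix::sparseMatrix(i = as.vector(trip$ii), j = as.vector(trip$jj),
                            x = as.vector(xx), dims = c(ndof, ndof))
  K <- Matrix::forceSymmetric(K, uplo = "U")
  fixed <- bc$fixed_dofs
  free <- setdiff(seq_len(ndof), fixed)
  u <- numeric(ndof)
  u[fixed] <- bc$values
  rhs <- f[free]
  if (any(bc$values != 0)) {
    rhs <- rhs - as.numeric(K[free, fixed, drop = FALSE] %*% bc$values)
  }
  Kff <- Matrix::forceSymmetric(K[free, free, drop = FALSE], uplo = "U")
  # reuse the symbolic Cholesky analysis across repeated solves on the
  # same mesh/BC pattern (remodeling changes values, not structure)
  ckey <- paste0("chol_", length(free), "_", bc$tag)
  uf <- tryCatch(suppressWarnings({
    ch <- mesh$cache[[ckey]]
    ch <- if (is.null(ch)) Matrix::Cholesky(Kff, LDL = FALSE) else
      Matrix::update(ch, Kff)
    mesh$cache[[ckey]] <- ch
    Matrix::solve(ch, rhs, system = "A")
  }), error = function(e) {
    stop("singular stiffness system (rigid-body modes not removed by ",
         "the boundary conditions): ", conditionMessage(e))
  })
  u[free] <- as.numeric(uf)
  # centroid strain recovery
  ue <- matrix(u[edof], nrow = nelem)
  ncomp <- if (nd == 2L) 3L else 6L
  strain <- matrix(0, nelem, ncomp)
  el_strain <- matrix(0, nelem, ncomp)
  stress <- matrix(0, nelem, ncomp)
  for (nu in unique(nus)) {
    g <- which(nus == nu)
    em <- elmat[[as.character(nu)]]
    eg <- ue[g, , drop = FALSE] %*% t(em$B_center)
    strain[g, ] <- eg
    ee <- eg - outer(eig0[g], em$ev)
    el_strain[g, ] <- ee
    stress[g, ] <- (ee %*% t(em$Dh)) * mat$modulus[g]
  }
  sed <- 0.5 * rowSums(stress * el_strain)
  sed[sed < 0 & sed > -1e-12] <- 0   # clip roundoff negatives
  structure(list(u = matrix(u, ncol = nd, byrow = TRUE), strain = strain,
                 elastic_strain = el_strain, stress = stress, sed = sed,
                 mode = mode),
            class = "field_state")
}

edof_matrix <- function(mesh) {
  nd <- mesh$nd
  nne <- ncol(mesh$elem)
  edof <- matrix(0L, nrow(mesh$elem), nne * nd)
  for (i in seq_len(nne)) {
    for (c_i in seq_len(nd)) {
      edof[, (i - 1L) * nd + c_i] <- (mesh$elem[, i] - 1L) * nd + c_i
    }
  }
  edof
}

#' Strain energy density from stress and elastic strain
#'
#' U = 1/2 sigma : eps, with the elastic strain (total minus swelling
#' eigenstrain) so that free swelling is energy-free.  Accepts symmetric
#' tensors as square matrices, or Voigt vectors with engineering shear
#' (length 3 in 2D, 6 in 3D), in which case the dot product already counts
#' shear twice.
#'
#' @param sigma Stress, MPa.
#' @param eps Elastic strain (dimensionless), same representation.
#' @return Strain energy density, J/cm^3 (= MPa).
#' @export
element_sed <- function(sigma, eps) {
  if (is.matrix(sigma) && nrow(sigma) == ncol(sigma)) {
    stopifnot(isTRUE(all.equal(sigma, t(sigma))),
              isTRUE(all.equal(eps, t(eps))))
    0.5 * sum(sigma * eps)
  } else {
    0.5 * sum(sigma * eps)
  }
}

#' Remodeling stimulus field S = U / rho
#'
#' @param state A \code{\link{field_state}} from
#'   \code{\link{solve_hygroelastic}}.
#' @param mat The \code{\link{material_state}} used in the solve.
#' @return Per-element stimulus in J/g; zero on anchor (non-remodeling)
#'   elements.  Errors if any remodeling element's density is below the
#'   floor (corrupted state).
#' @export
stimulus_field <- function(state, mat) {
  S <- numeric(length(state$sed))
  b <- mat$remodels
  if (any(mat$density[b] < mat$cal$rho_min - 1e-12)) {
    stop("density below rho_min; material state is corrupted")
  }
  S[b] <- pmax(state$sed[b], 0) / mat$density[b]
  S
}

#' Analytic shrink-fit interface pressure (plane stress)
#'
#' Closed-form Lame solution for a solid inner disc that would freely
#' expand by radial strain \code{e}, pressed inside an annulus with free
#' outer radius \code{b}:
#' \deqn{p = e / [ (b^2+a^2)/(E_o(b^2-a^2)) + \nu_o/E_o + (1-\nu_i)/E_i ]}
#' This is the independent oracle against which the finite element
#' constrained-swelling pressure is verified on a two-material disc.
#'
#' @param a Interface (inner) radius, mm; \code{0 < a < b}.
#' @param b Outer radius of the annulus, mm.
#' @param E_i,nu_i Inner disc modulus (MPa) and Poisson ratio.
#' @param E_o,nu_o Annulus modulus (MPa) and Poisson ratio.
#' @param free_radial_strain Unconstrained radial expansion strain of the
#'   inner disc (for swelling, beta * dalpha).
#' @return Interface pressure, MPa (positive = compression).
#' @export
lame_shrinkfit_oracle <- function(a, b, E_i, nu_i, E_o, nu_o,
                                  free_radial_strain) {
  if (a <= 0 || a >= b) stop("require 0 < a < b")
  denom <- (b^2 + a^2) / (E_o * (b^2 - a^2)) + nu_o / E_o + (1 - nu_i) / E_i
  free_radial_strain / denom
}
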