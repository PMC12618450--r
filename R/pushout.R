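#' Bone--anchor interface facets
#'
#' Finds the element faces shared by an anchor element and a bone element.
#' Each facet records both element ids, its center (mm), its area (mm^2;
#' unit out-of-plane thickness in 2D), and the outward unit normal of the
#' nominal anchor surface at the facet center (radial from the anchor
#' axis), which is the direction in which contact pressure acts.
#'
#' @param mesh A \code{\link{voxel_mesh}} containing both regions.
#' @param axis_center In-plane coordinates of the anchor axis, mm
#'   (length 2). Default: centroid of the anchor elements.
#' @param axis Drill axis in 3D (1, 2 or 3; default 3). Ignored in 2D.
#' @return A data frame with columns \code{bone_elem}, \code{anchor_elem},
#'   facet center coordinates, normal components, and \code{area}.
#' @export
interface_facets <- function(mesh, axis_center = NULL, axis = 3L) {
  d <- mesh$grid_dim
  nd <- mesh$nd
  elem_of_voxel <- integer(prod(d))
  elem_of_voxel[mesh$voxel_index] <- seq_along(mesh$voxel_index)
  vox <- arrayInd(mesh$voxel_index, d)          # 1-based voxel indices
  anchors <- which(mesh$region == "anchor")
  if (length(anchors) == 0) stop("mesh has no anchor elements")
  plane <- if (nd == 3L) setdiff(1:3, axis) else 1:2
  if (is.null(axis_center)) {
    axis_center <- colMeans(mesh$centroid[anchors, plane, drop = FALSE])
  }
  rows <- list()
  for (ax in seq_len(nd)) {
    for (dir in c(-1L, 1L)) {
      nb <- vox[anchors, , drop = FALSE]
      nb[, ax] <- nb[, ax] + dir
      ok <- nb[, ax] >= 1L & nb[, ax] <= d[ax]
      lin <- rep(0L, length(anchors))
      if (any(ok)) {
        lin[ok] <- as.integer(
          1 + (nb[ok, , drop = FALSE] - 1L) %*%
            cumprod(c(1L, d[-nd]))
        )
      }
      nbe <- ifelse(ok & lin > 0, elem_of_voxel[pmax(lin, 1L)], 0L)
      hit <- which(nbe > 0 &
                     mesh$region[pmax(nbe, 1L)] %in% c("bone", "marrow"))
      if (length(hit) == 0) next
      ae <- anchors[hit]
      be <- nbe[hit]
      ctr <- mesh$centroid[ae, , drop = FALSE]
      ctr[, ax] <- ctr[, ax] + dir * mesh$h / 2
      rows[[length(rows) + 1L]] <- data.frame(
        bone_elem = be, anchor_elem = ae, ctr = I(ctr),
        face_axis = ax, face_dir = dir)
    }
  }
  if (length(rows) == 0) stop("no bone-anchor interface facets found")
  fac <- do.call(rbind, rows)
  ctr <- do.call(rbind, lapply(seq_len(nrow(fac)), function(i) fac$ctr[i, ]))
  # radial outward normal of the nominal cylindrical interface
  nrm <- matrix(0, nrow(fac), nd)
  rad <- ctr[, plane, drop = FALSE] -
    matrix(axis_center, nrow(fac), 2, byrow = TRUE)
  len <- sqrt(rowSums(rad^2))
  len[len == 0] <- 1
  nrm[, plane] <- rad / len
  out <- data.frame(bone_elem = fac$bone_elem, anchor_elem = fac$anchor_elem)
  for (i in seq_len(nd)) out[[paste0("c", i)]] <- ctr[, i]
  for (i in seq_len(nd)) out[[paste0("n", i)]] <- nrm[, i]
  out$face_axis <- fac$face_axis
  out$face_dir <- fac$face_dir
  out$area <- mesh$h^(nd - 1)
  out
}

#' Interface normal contact pressure
#'
#' Evaluates p = -n . sigma . n at each interface facet, with n the
#' outward (radial) normal of the nominal anchor surface.  The normal
#' traction is continuous across the tied interface, so the default facet
#' stress is the mean of the two adjacent element stresses; this cancels
#' the leading-order staircase stress oscillation of the voxelised
#' boundary (the single-side estimates carry opposite-signed O(1) local
#' errors).  Positive values are compression; tensile facets are reported
#' as negative and excluded later from the friction integral (open
#' contact).
#'
#' @param state A \code{\link{field_state}}.
#' @param mesh The \code{\link{voxel_mesh}} of the solve.
#' @param facets Facet table from \code{\link{interface_facets}}.
#' @param side Which element stress to evaluate: \code{"both"} (two-side
#'   mean, default), \code{"bone"} or \code{"anchor"}.
#' @return Numeric vector of facet pressures, MPa.
#' @export
interface_normal_pressure <- function(state, mesh, facets,
                                      side = c("both", "bone", "anchor")) {
  side <- match.arg(side)
  nd <- mesh$nd
  snn_of <- function(el) {
    s <- state$stress[el, , drop = FALSE]
    if (nd == 2L) {
      nx <- facets$n1; ny <- facets$n2
      s[, 1] * nx^2 + s[, 2] * ny^2 + 2 * s[, 3] * nx * ny
    } else {
      nx <- facets$n1; ny <- facets$n2; nz <- facets$n3
      s[, 1] * nx^2 + s[, 2] * ny^2 + s[, 3] * nz^2 +
        2 * (s[, 4] * nx * ny + s[, 5] * ny * nz + s[, 6] * nz * nx)
    }
  }
  snn <- switch(side,
    bone = snn_of(facets$bone_elem),
    anchor = snn_of(facets$anchor_elem),
    both = (snn_of(facets$bone_elem) + snn_of(facets$anchor_elem)) / 2)
  -snn
}

#' Coulomb friction push-out force
#'
#' F = mu * sum(max(p, 0) * A): only compressive facets resist sliding.
#'
#' @param pressures Facet pressures, MPa.
#' @param areas Facet areas, mm^2 (recycled if scalar).
#' @param mu Friction coefficient (non-negative), default 0.4.
#' @return Push-out force in N (per mm thickness for 2D meshes).
#' @export
coulomb_pushout_force <- function(pressures, areas, mu = 0.4) {
  if (mu < 0) stop("negative friction coefficient")
  areas <- rep_len(areas, length(pressures))
  mu * sum(pmax(pressures, 0) * areas)
}

#' Push-out estimate for one mechanical state
#'
#' @param state A \code{\link{field_state}}.
#' @param mesh The \code{\link{voxel_mesh}}.
#' @param facets Facet table from \code{\link{interface_facets}}.
#' @param mu Friction coefficient, default 0.4.
#' @return An object of class \code{"pushout_estimate"} with facet
#'   pressures, areas, and the Coulomb force.
#' @export
pushout_estimate <- function(state, mesh, facets, mu = 0.4) {
  p <- interface_normal_pressure(state, mesh, facets)
  structure(list(mu = mu, pressures = p, areas = facets$area,
                 force = coulomb_pushout_force(p, facets$area, mu)),
            class = "pushout_estimate")
}

#' Relative fixation change between pre- and post-remodeling states
#'
#' @param pre,post \code{\link{pushout_estimate}} objects on the same
#'   interface.
#' @return A list with \code{f_pre}, \code{f_post} (N) and
#'   \code{relative_change} = (F_post - F_pre) / F_pre.
#' @export
compare_fixation <- function(pre, post) {
  stopifnot(inherits(pre, "pushout_estimate"),
            inherits(post, "pushout_estimate"),
            length(pre$pressures) == length(post$pressures))
  if (pre$force == 0) stop("pre-remodeling force is zero")
  list(f_pre = pre$force, f_post = post$force,
       relative_change = (post$force - pre$force) / pre$force)
}
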