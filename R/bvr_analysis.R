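#' Hollow-cylinder ROI mask at the bone--implant interface
#'
#' Voxels whose centers satisfy inner_radius <= r < inner_radius +
#' thickness (half-open, so adjacent shells never double count) and, for
#' 3D images, lie within the axial height band measured down from the top
#' surface.  The default geometry is the 2-mm shell adjacent to an 8-mm
#' anchor.
#'
#' @param image An \code{\link{hu_image}}.
#' @param center In-plane axis position, mm (length 2).
#' @param inner_radius Inner radius, mm (default 4, the anchor radius).
#' @param thickness Radial thickness, mm (> 0; default 2).
#' @param height Axial extent from the top surface, mm (default 10, the
#'   defect depth); ignored for 2D images.
#' @param axis Cylinder axis for 3D images (default 3).
#' @return An object of class \code{"roi_mask"}: logical voxel mask,
#'   shape tag, parameters and ROI volume \code{v0} (mm^3; mm^2 times unit
#'   thickness in 2D).
#' @export
hollow_cylinder_mask <- function(image, center, inner_radius = 4,
                                 thickness = 2, height = 10, axis = 3L) {
  if (thickness <= 0) stop("thickness must be positive (empty mask)")
  d <- dim(image$values)
  nd <- length(d)
  h <- image$voxel_size
  plane <- if (nd == 3L) setdiff(1:3, axis) else 1:2
  cc <- lapply(seq_len(nd), function(i) {
    voxel_centers(d[i], h, image$origin[i])
  })
  r2 <- outer((cc[[plane[1]]] - center[1])^2,
              (cc[[plane[2]]] - center[2])^2, `+`)
  ring <- r2 >= inner_radius^2 & r2 < (inner_radius + thickness)^2
  mask <- if (nd == 3L) {
    top <- image$origin[axis] + d[axis] * h
    in_h <- cc[[axis]] > top - height
    aperm(array(outer(ring, in_h) > 0, dim = c(d[plane], d[axis])),
          order(c(plane, axis)))
  } else {
    ring
  }
  if (!any(mask)) stop("empty ROI mask")
  roi_mask(mask, "hollow_cylinder", image,
           params = list(center = center, inner_radius = inner_radius,
                         thickness = thickness, height = height))
}

roi_mask <- function(mask, shape, image, params) {
  nd <- length(dim(mask))
  structure(list(mask = mask, shape = shape,
                 v0 = sum(mask) * image$voxel_size^nd,
                 voxel_size = image$voxel_size, params = params),
            class = "roi_mask")
}

#' Spherical ROI of prescribed volume
#'
#' Places a sphere (disc in 2D) of closed-form radius
#' \eqn{r = (3 V_0 / 4\pi)^{1/3}} (2D: \eqn{\sqrt{V_0/\pi}}) so its
#' voxelised volume matches the reference ROI volume \code{v0}; used for
#' the equal-volume far-field comparison ROIs.
#'
#' @param image An \code{\link{hu_image}}.
#' @param center Sphere center, mm (length = image dimensionality).
#' @param v0 Target volume, mm^3 (2D: area in mm^2).
#' @return An \code{\link{hu_image}}-aligned \code{"roi_mask"}.
#' @export
equal_volume_sphere_mask <- function(image, center, v0) {
  d <- dim(image$values)
  nd <- length(d)
  h <- image$voxel_size
  radius <- if (nd == 3L) (3 * v0 / (4 * pi))^(1 / 3) else sqrt(v0 / pi)
  lo <- image$origin
  hi <- image$origin + d * h
  if (any(center - radius < lo) || any(center + radius > hi)) {
    stop("sphere of radius ", round(radius, 2), " mm does not fit at this ",
         "center")
  }
  cc <- lapply(seq_len(nd), function(i) {
    voxel_centers(d[i], h, image$origin[i])
  })
  r2 <- outer((cc[[1]] - center[1])^2, (cc[[2]] - center[2])^2, `+`)
  if (nd == 3L) {
    r2 <- outer(r2, (cc[[3]] - center[3])^2, `+`)
  }
  mask <- r2 < radius^2
  if (!any(mask)) {
    # degenerate target below one voxel: take the voxel containing center
    idx <- pmin(pmax(floor((center - image$origin) / h) + 1, 1), d)
    mask <- array(FALSE, dim = d)
    mask[matrix(idx, 1)] <- TRUE
  }
  roi_mask(mask, "sphere", image,
           params = list(center = center, radius = radius, v0_target = v0))
}

#' Bone volume ratio of an ROI by HU thresholding
#'
#' ratio = (# ROI voxels with HU inside the bone band) / (# ROI voxels).
#'
#' @param image An \code{\link{hu_image}}.
#' @param roi An \code{"roi_mask"} aligned to the image.
#' @param hu_band HU interval classifying bone; defaults to the image's
#'   declared band.
#' @param label Optional label (\code{"interface"} or \code{"far"}).
#' @return A list with \code{v_bone} (mm^3), \code{v0}, \code{ratio} and
#'   \code{label}.
#' @export
bone_volume_ratio <- function(image, roi, hu_band = image$hu_bone,
                              label = NA_character_) {
  stopifnot(inherits(roi, "roi_mask"),
            all(dim(roi$mask) == dim(image$values)))
  if (hu_band[1] >= hu_band[2]) stop("hu_band lower bound must be < upper")
  n <- sum(roi$mask)
  if (n == 0) stop("empty ROI")
  vals <- image$values[roi$mask]
  nb <- sum(vals >= hu_band[1] & vals <= hu_band[2])
  nd <- length(dim(image$values))
  list(v_bone = nb * image$voxel_size^nd, v0 = roi$v0, ratio = nb / n,
       label = label)
}

#' Paired comparison of interface vs far-field bone volume ratios
#'
#' Classical paired t-test on the per-specimen differences, with summary
#' statistics.  Degenerate zero-variance differences are resolved by the
#' limit of the t statistic: identical lists give t = 0, p = 1; a nonzero
#' constant difference gives p -> 0 with a flag.
#'
#' @param interface_ratios,far_ratios Equal-length numeric vectors
#'   (n >= 2) of per-specimen V1/V0 and V2/V0.
#' @return A list with per-group mean and sd, \code{t}, \code{df},
#'   \code{p_value}, \code{mean_difference}, and \code{degenerate} flag.
#' @export
paired_comparison <- function(interface_ratios, far_ratios) {
  n <- length(interface_ratios)
  if (length(far_ratios) != n) stop("unequal group lengths")
  if (n < 2) stop("paired comparison needs n >= 2")
  d <- interface_ratios - far_ratios
  out <- list(
    n = n,
    interface_mean = mean(interface_ratios),
    interface_sd = stats::sd(interface_ratios),
    far_mean = mean(far_ratios), far_sd = stats::sd(far_ratios),
    mean_difference = mean(d), df = n - 1, degenerate = FALSE)
  if (stats::sd(d) == 0) {
    out$degenerate <- TRUE
    if (mean(d) == 0) {
      out$t <- 0; out$p_value <- 1
    } else {
      out$t <- sign(mean(d)) * Inf; out$p_value <- 0
    }
  } else {
    tt <- stats::t.test(interface_ratios, far_ratios, paired = TRUE)
    out$t <- unname(tt$statistic)
    out$p_value <- tt$p.value
  }
  out
}

#' Project a remodeled density field back to an HU image
#'
#' Inverts the linear HU-to-density calibration elementwise on a voxel
#' mesh, producing a synthetic HU grid that the same BVR pipeline can
#' analyse as if it were a follow-up scan.  Voxels outside the mesh (and
#' anchor voxels) receive the background HU.
#'
#' @param mat Final \code{\link{material_state}}.
#' @param mesh The \code{\link{voxel_mesh}} the state lives on.
#' @param cal Calibration to invert; defaults to the state's.
#' @param hu_background HU for non-bone voxels.
#' @return An \code{\link{hu_image}} with the mesh's grid geometry.
#' @export
density_to_hu_projection <- function(mat, mesh, cal = mat$cal,
                                     hu_background = 0) {
  vals <- array(hu_background, dim = mesh$grid_dim)
  b <- mat$remodels
  vals[mesh$voxel_index[b]] <- density_to_hu(mat$density[b], cal)
  hu_image(vals, mesh$h, mesh$origin, hu_background = hu_background)
}
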