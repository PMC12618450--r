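#' HU voxel image
#'
#' A regular isotropic voxel grid of Hounsfield-unit values, the package's
#' stand-in for a micro-CT scan.  Voxel indices are 0-based; the physical
#' corner of voxel (0,0,...) is \code{origin} and voxel centers sit at
#' \code{origin + (index + 0.5) * voxel_size}.  All geometric membership
#' tests (defect cylinders, ROI masks) are evaluated at voxel centers.
#'
#' @param values Numeric 2D or 3D array of HU values (finite).
#' @param voxel_size Isotropic voxel edge length, mm (positive).
#' @param origin Physical coordinate of the (0,0,...) voxel corner, mm.
#' @param hu_bone Two-element HU interval classifying bone voxels.
#' @param hu_background HU value of non-bone (marrow/void) space.
#' @return An object of class \code{"hu_image"}.
#' @export
hu_image <- function(values, voxel_size, origin = rep(0, length(dim(values))),
                     hu_bone = c(200, 1000), hu_background = 0) {
  d <- dim(values)
  if (is.null(d) || !length(d) %in% c(2L, 3L)) {
    stop("values must be a 2D or 3D array")
  }
  stopifnot(all(d >= 1), voxel_size > 0, all(is.finite(values)),
            length(origin) == length(d), hu_bone[1] < hu_bone[2])
  structure(list(values = values, voxel_size = voxel_size, origin = origin,
                 hu_bone = hu_bone, hu_background = hu_background),
            class = "hu_image")
}

#' @export
print.hu_image <- function(x, ...) {
  d <- dim(x$values)
  cat("<hu_image> ", paste(d, collapse = " x "), " voxels @ ",
      x$voxel_size, " mm (", paste(round(d * x$voxel_size, 2),
      collapse = " x "), " mm)\n", sep = "")
  cat("  HU range [", round(min(x$values), 1), ", ",
      round(max(x$values), 1), "], bone band [", x$hu_bone[1], ", ",
      x$hu_bone[2], "]\n", sep = "")
  invisible(x)
}

# voxel-center coordinates along one axis (mm)
voxel_centers <- function(n, voxel_size, origin) {
  origin + (seq_len(n) - 0.5) * voxel_size
}

# separable Gaussian smoothing of a 2D/3D array; sigma in voxels.
# Truncated kernel, rows renormalised (renormalised-boundary convolution).
gauss_smooth_array <- function(a, sigma) {
  if (sigma <= 0) return(a)
  d <- dim(a)
  nd <- length(d)
  smooth_mat <- function(n) {
    half <- max(1L, ceiling(3 * sigma))
    i <- seq_len(n)
    K <- outer(i, i, function(r, c) {
      w <- exp(-((r - c)^2) / (2 * sigma^2))
      w * (abs(r - c) <= half)
    })
    K / rowSums(K)
  }
  for (ax in seq_len(nd)) {
    perm <- c(ax, setdiff(seq_len(nd), ax))
    ap <- aperm(a, perm)
    dp <- dim(ap)
    m <- smooth_mat(dp[1]) %*% matrix(ap, nrow = dp[1])
    dim(m) <- dp
    a <- aperm(m, order(perm))
  }
  a
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Generate a synthetic trabecular HU image
#'
#' Gaussian white noise is smoothed with an isotropic Gaussian kernel of
#' width \code{correlation_length} and thresholded at the empirical quantile
#' that realises \code{target_bvr}, giving a connected, trabeculae-like
#' two-phase structure with a controlled bone volume ratio.  Bone voxels
#' receive HU on a linear ramp with (voxel) distance from the void phase --
#' strut cores read denser than strut surfaces -- clipped to \code{hu_bone};
#' background voxels receive \code{hu_background}.  All randomness flows
#' through \code{seed}; the caller's RNG state is untouched.
#'
#' @param shape Grid dimensions, length 2 or 3, all >= 1.
#' @param voxel_size Isotropic voxel edge, mm. The default 0.25 mm keeps
#'   downstream finite element problems at desk scale.
#' @param target_bvr Target bone volume ratio in (0, 1].
#' @param correlation_length Smoothing kernel width, mm
#'   (>= \code{voxel_size}).
#' @param hu_bone HU interval assigned to bone, default c(200, 1000).
#' @param hu_background HU of background voxels, default 0.
#' @param seed Integer seed; identical seeds give bit-identical images.
#' @param origin Physical origin, mm.
#' @return An \code{\link{hu_image}}.
#' @export
generate_trabecular_image <- function(shape, voxel_size = 0.25,
                                      target_bvr = 0.47,
                                      correlation_length = 0.6,
                                      hu_bone = c(200, 1000),
                                      hu_background = 0, seed = 1,
                                      origin = rep(0, length(shape))) {
  if (any(shape < 1)) stop("non-positive shape")
  if (target_bvr <= 0 || target_bvr > 1) stop("target_bvr outside (0, 1]")
  if (correlation_length < voxel_size) {
    stop("correlation_length must be >= voxel_size")
  }
  shape <- as.integer(shape)
  field <- with_seed(seed, {
    noise <- array(stats::rnorm(prod(shape)), dim = shape)
    gauss_smooth_array(noise, correlation_length / voxel_size)
  })
  thr <- stats::quantile(field, probs = 1 - target_bvr, names = FALSE,
                         type = 7)
  bone <- field >= thr
  dist <- erosion_distance(bone)
  vals <- array(hu_background, dim = shape)
  if (any(bone)) {
    dmax <- max(dist)
    ramp <- if (dmax > 1) (dist[bone] - 1) / (dmax - 1) else 0.5
    vals[bone] <- pmin(pmax(hu_bone[1] + ramp * (hu_bone[2] - hu_bone[1]),
                            hu_bone[1]), hu_bone[2])
  }
  hu_image(vals, voxel_size, origin, hu_bone, hu_background)
}

# integer distance (in voxels, face-connected) from the void phase,
# computed by iterative morphological erosion; 0 for void voxels,
# 1 for bone voxels touching void, etc.  Array boundary is treated as bone
# (replicate padding), so edge struts are not artificially surface-like.
erosion_distance <- function(mask) {
  d <- dim(mask)
  nd <- length(d)
  shift_min <- function(m) {
    out <- m
    for (ax in seq_len(nd)) {
      for (dir in c(-1L, 1L)) {
        idx <- lapply(d, seq_len)
        src <- idx
        n <- d[ax]
        take <- pmin(pmax(seq_len(n) + dir, 1L), n)  # replicate at edges
        src[[ax]] <- take
        out <- out & do.call(`[`, c(list(m), src, list(drop = FALSE)))
      }
    }
    out
  }
  dist <- array(0L, dim = d)
  cur <- mask
  k <- 0L
  while (any(cur)) {
    k <- k + 1L
    dist[cur] <- k
    cur <- shift_min(cur)
    if (k > max(d)) break  # cannot erode deeper than the grid
  }
  dist
}

#' Defect and anchor geometry
#'
#' A cylindrical surgical defect drilled along a grid axis, containing a
#' coaxial cylindrical anchor.  In 2D images the cylinder degenerates to a
#' disc and \code{depth} is ignored.
#'
#' @param center In-plane center of the cylinder axis, mm (length 2 for the
#'   axes perpendicular to \code{axis}; for 2D images the disc center).
#' @param diameter Drill diameter, mm (positive); default 8.
#' @param depth Drill depth from the top (max-index) surface along
#'   \code{axis}, mm; default 10.
#' @param anchor_diameter Anchor diameter, mm, \code{<= diameter};
#'   default equal to \code{diameter} (press-fit, no void ring).
#' @param axis Drill axis for 3D images: 1, 2 or 3 (default 3).
#' @return An object of class \code{"defect_spec"}.
#' @export
defect_spec <- function(center, diameter = 8, depth = 10,
                        anchor_diameter = diameter, axis = 3L) {
  stopifnot(diameter > 0, depth > 0, anchor_diameter >= 0,
            anchor_diameter <= diameter, axis %in% 1:3)
  structure(list(center = center, diameter = diameter, depth = depth,
                 anchor_diameter = anchor_diameter, axis = as.integer(axis)),
            class = "defect_spec")
}

#' Drill the surgical defect and insert the anchor
#'
#' Voxels inside the defect cylinder are set to the background HU and
#' labeled \code{"void"}; voxels inside the coaxial anchor cylinder are
#' labeled \code{"anchor"}; all remaining voxels are labeled \code{"bone"}
#' or \code{"marrow"} by the image's HU band.  Membership is tested at
#' voxel centers, with half-open radial intervals.  The operation is
#' idempotent on the labeled region.
#'
#' @param image An \code{\link{hu_image}}.
#' @param defect A \code{\link{defect_spec}} lying inside the image.
#' @return A list with \code{image} (drilled \code{hu_image}) and
#'   \code{labels} (character array of region labels, same dim).
#' @export
drill_and_insert <- function(image, defect) {
  stopifnot(inherits(image, "hu_image"), inherits(defect, "defect_spec"))
  d <- dim(image$values)
  nd <- length(d)
  h <- image$voxel_size
  ax <- if (nd == 3L) defect$axis else NA_integer_
  plane <- if (nd == 3L) setdiff(1:3, ax) else 1:2
  stopifnot(length(defect$center) == 2)
  # radial distance of voxel centers from the axis, in the drill plane
  cc <- lapply(seq_len(nd), function(i) voxel_centers(d[i], h, image$origin[i]))
  r2 <- outer((cc[[plane[1]]] - defect$center[1])^2,
              (cc[[plane[2]]] - defect$center[2])^2, `+`)
  rad <- defect$diameter / 2
  ext_lo <- image$origin[plane] + 0
  ext_hi <- image$origin[plane] + d[plane] * h
  if (any(defect$center - rad < ext_lo) || any(defect$center + rad > ext_hi)) {
    stop("defect extends outside the image grid")
  }
  in_circle <- r2 < rad^2
  in_anchor <- r2 < (defect$anchor_diameter / 2)^2
  if (nd == 3L) {
    top <- image$origin[ax] + d[ax] * h
    if (defect$depth > d[ax] * h) stop("defect deeper than the image grid")
    zc <- voxel_centers(d[ax], h, image$origin[ax])
    in_depth <- zc > top - defect$depth
    expand <- function(circle) {
      # broadcast the in-plane mask along the axis, gated by depth
      perm <- c(plane, ax)
      m <- outer(circle, in_depth) > 0
      aperm(array(m, dim = c(d[plane], d[ax])), order(perm))
    }
    void_mask <- expand(in_circle)
    anchor_mask <- expand(in_anchor)
  } else {
    void_mask <- in_circle
    anchor_mask <- in_anchor
  }
  labels <- array("marrow", dim = d)
  labels[image$values >= image$hu_bone[1] &
           image$values <= image$hu_bone[2]] <- "bone"
  vals <- image$values
  vals[void_mask] <- image$hu_background
  labels[void_mask] <- "void"
  labels[anchor_mask] <- "anchor"
  out <- image
  out$values <- vals
  list(image = out, labels = labels)
}

#' HU histogram of an image
#'
#' @param image An \code{\link{hu_image}}.
#' @param n_breaks Number of histogram bins.
#' @return A data frame with bin midpoints and counts, suitable for CSV
#'   export.
#' @export
hu_histogram <- function(image, n_breaks = 50) {
  hgram <- graphics::hist(image$values, breaks = n_breaks, plot = FALSE)
  data.frame(hu_mid = hgram$mids, count = hgram$counts)
}

#' Write an HU image as a multi-page TIFF with a sidecar header
#'
#' The voxel values are stored as 16-bit grayscale pages (one page per
#' z-slice; a single page for 2D images), linearly rescaled to [0, 1]; the
#' rescaling interval, voxel size, origin and HU bands are recorded in a
#' YAML sidecar (\code{<path>.yml}) so the image round-trips exactly to
#' 16-bit quantisation.
#'
#' @param image An \code{\link{hu_image}}.
#' @param path Output TIFF path.
#' @return Invisibly, the sidecar path.
#' @export
write_hu_tiff <- function(image, path) {
  v <- image$values
  lo <- min(v); hi <- max(v)
  scale <- if (hi > lo) hi - lo else 1
  norm <- (v - lo) / scale
  d <- dim(v)
  pages <- if (length(d) == 3L) {
    lapply(seq_len(d[3]), function(z) t(norm[, , z])[, , drop = TRUE])
  } else {
    list(t(norm))
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  sidecar <- paste0(path, ".yml")
  yaml::write_yaml(list(dims = as.integer(d), voxel_size = image$voxel_size,
                        origin = as.numeric(image$origin),
                        hu_bone = as.numeric(image$hu_bone),
                        hu_background = image$hu_background,
                        hu_min = lo, hu_scale = scale), sidecar)
  invisible(sidecar)
}

#' Read an HU image written by \code{write_hu_tiff}
#'
#' @param path TIFF path with an accompanying \code{<path>.yml} sidecar.
#' @return An \code{\link{hu_image}}.
#' @export
read_hu_tiff <- function(path) {
  meta <- yaml::read_yaml(paste0(path, ".yml"))
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d <- as.integer(meta$dims)
  arr <- if (length(d) == 3L) {
    a <- array(0, dim = d)
    for (z in seq_len(d[3])) a[, , z] <- t(pages[[z]])
    a
  } else {
    t(pages[[1]])
  }
  vals <- arr * meta$hu_scale + meta$hu_min
  hu_image(vals, meta$voxel_size, meta$origin,
           hu_bone = meta$hu_bone, hu_background = meta$hu_background)
}
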