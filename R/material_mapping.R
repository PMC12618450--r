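#' Calibration constants linking Hounsfield units to bone material properties
#'
#' Apparent bone density and elastic modulus are taken to vary linearly with
#' the CT attenuation value (Hounsfield units, HU).  The published empirical
#' coefficients are expressed in g/m^3 and Pa; this package converts them at
#' the calibration boundary to its canonical unit system (length mm, force N,
#' stress MPa, density g/cm^3), so that strain energy density comes out in
#' J/cm^3 and the remodeling stimulus U/rho in J/g with no hidden factors.
#'
#' @param density_intercept Density at HU = 0, in g/m^3.
#' @param density_slope Density increase per HU, in g/m^3 per HU.
#' @param modulus_intercept Modulus at zero density, in Pa.
#' @param modulus_slope Modulus increase per unit density, in Pa per (g/m^3).
#' @param rho_min,rho_max Apparent-density bounds, g/cm^3.  Densities are
#'   clamped to this interval both at mapping time and during remodeling so
#'   the initial and evolved states share one invariant.
#' @return An object of class \code{"calibration_constants"}.
#' @export
calibration_constants <- function(density_intercept = 1041395,
                                  density_slope = 1017,
                                  modulus_intercept = -388.8,
                                  modulus_slope = 5925,
                                  rho_min = 0.01,
                                  rho_max = 2.0) {
  stopifnot(density_slope > 0, modulus_slope > 0, rho_min < rho_max,
            rho_min > 0)
  structure(list(density_intercept = density_intercept,
                 density_slope = density_slope,
                 modulus_intercept = modulus_intercept,
                 modulus_slope = modulus_slope,
                 rho_min = rho_min, rho_max = rho_max),
            class = "calibration_constants")
}

#' Convert Hounsfield units to apparent density
#'
#' Applies the linear HU-to-density calibration and converts g/m^3 to
#' g/cm^3 (divide by 1e6), then clamps to the remodeling density bounds.
#'
#' @param hu Numeric vector of Hounsfield units (finite).
#' @param cal A \code{\link{calibration_constants}} object.
#' @return Apparent density in g/cm^3, clamped to \code{[rho_min, rho_max]}.
#' @export
hu_to_density <- function(hu, cal = calibration_constants()) {
  stopifnot(is.numeric(hu), all(is.finite(hu)))
  rho <- (cal$density_intercept + cal$density_slope * hu) / 1e6
  pmin(pmax(rho, cal$rho_min), cal$rho_max)
}

#' Convert apparent density to elastic modulus
#'
#' Applies the linear density-to-modulus calibration.  Density enters in
#' g/cm^3, is converted to g/m^3 internally, and the resulting modulus in Pa
#' is returned in MPa.  The same map is used for the initial HU-based
#' assignment and for the stiffness update after each remodeling increment.
#'
#' @param density Apparent density in g/cm^3 (positive).
#' @param cal A \code{\link{calibration_constants}} object.
#' @return Elastic modulus in MPa.
#' @export
density_to_modulus <- function(density, cal = calibration_constants()) {
  stopifnot(is.numeric(density), all(is.finite(density)), all(density > 0))
  e_mpa <- (cal$modulus_intercept + cal$modulus_slope * density * 1e6) / 1e6
  if (any(e_mpa <= 0)) {
    stop("non-positive modulus from density ", min(density),
         " g/cm^3; material state is corrupted (density below the floor)")
  }
  e_mpa
}

#' Invert the density calibration back to Hounsfield units
#'
#' @param density Apparent density in g/cm^3.
#' @param cal A \code{\link{calibration_constants}} object.
#' @return Hounsfield units such that \code{hu_to_density} recovers
#'   \code{density} (within the clamp range).
#' @export
density_to_hu <- function(density, cal = calibration_constants()) {
  (density * 1e6 - cal$density_intercept) / cal$density_slope
}

#' Bin a density field into discrete material types
#'
#' Reproduces the discrete-material workflow in which the HU histogram is
#' split into a small number of types (ten in the reference workflow), each
#' represented by one density/modulus pair.  Binning is optional: continuous
#' per-element properties are the package default, and this function exists
#' to emulate the binned assignment.
#'
#' @param densities Per-element apparent densities, g/cm^3 (non-empty).
#' @param n_bins Number of equal-width bins spanning the density range.
#' @param cal A \code{\link{calibration_constants}} object.
#' @return A list with \code{bin_index} (1..n_bins per element),
#'   \code{bin_density} (bin-midpoint representative densities) and
#'   \code{bin_modulus} (moduli of the representatives).
#' @export
bin_materials <- function(densities, n_bins = 10,
                          cal = calibration_constants()) {
  if (length(densities) == 0) stop("empty density field")
  stopifnot(n_bins >= 1)
  lo <- min(densities); hi <- max(densities)
  if (hi == lo) {
    # degenerate constant field: a single occupied bin at the field value
    idx <- rep(1L, length(densities))
    mid <- rep(lo, n_bins)
  } else {
    width <- (hi - lo) / n_bins
    idx <- pmin(pmax(floor((densities - lo) / width) + 1, 1L), n_bins)
    mid <- lo + (seq_len(n_bins) - 0.5) * width
  }
  list(bin_index = as.integer(idx),
       bin_density = mid,
       bin_modulus = density_to_modulus(mid, cal))
}

#' Per-element material state
#'
#' Bundles the evolving per-element fields: apparent density (g/cm^3),
#' Young's modulus (MPa), Poisson ratio, and a logical flag marking the
#' elements that remodel (bone/marrow, not the anchor).
#'
#' @param density Per-element apparent density, g/cm^3.
#' @param modulus Per-element Young's modulus, MPa (positive).
#' @param poisson Per-element (or scalar) Poisson ratio.
#' @param remodels Logical per-element flag; \code{FALSE} for anchor elements.
#' @param cal Calibration used for stiffness updates.
#' @return An object of class \code{"material_state"}.
#' @export
material_state <- function(density, modulus, poisson = 0.3,
                           remodels = rep(TRUE, length(density)),
                           cal = calibration_constants()) {
  n <- length(density)
  poisson <- rep_len(poisson, n)
  stopifnot(length(modulus) == n, length(remodels) == n,
            all(modulus > 0), all(poisson > 0), all(poisson < 0.5))
  if (any(density[remodels] < cal$rho_min - 1e-12) ||
      any(density[remodels] > cal$rho_max + 1e-12)) {
    stop("bone density outside [rho_min, rho_max]")
  }
  structure(list(density = density, modulus = modulus, poisson = poisson,
                 remodels = remodels, cal = cal),
            class = "material_state")
}

#' Build a material state from an HU image and element region labels
#'
#' Bone elements receive HU-calibrated density and modulus.  Marrow (pore
#' space) elements are by default also HU-calibrated -- they carry the low
#' background HU, mirroring the gap-filled heterogeneous workflow used
#' with real scans, in which the filled space compensates through its
#' calibrated properties and remodels like bone -- or can be started at an
#' explicit \code{rho_marrow}.  Anchor elements receive the fixed
#' swollen-polymer modulus and never remodel.
#'
#' @param hu Per-element Hounsfield units.
#' @param region Per-element region labels: \code{"bone"}, \code{"marrow"}
#'   or \code{"anchor"}.
#' @param e_anchor Modulus of the (swollen) anchor polymer, MPa.
#' @param poisson Poisson ratio used for all regions.
#' @param rho_marrow Optional initial apparent density of marrow elements,
#'   g/cm^3; \code{NULL} (default) calibrates marrow from its HU.
#' @param cal A \code{\link{calibration_constants}} object.
#' @return A \code{\link{material_state}}.
#' @export
material_from_hu <- function(hu, region, e_anchor = 50, poisson = 0.3,
                             rho_marrow = NULL,
                             cal = calibration_constants()) {
  stopifnot(length(hu) == length(region),
            all(region %in% c("bone", "marrow", "anchor")))
  rho <- hu_to_density(hu, cal)
  if (!is.null(rho_marrow)) rho[region == "marrow"] <- rho_marrow
  e <- density_to_modulus(rho, cal)
  anchor <- region == "anchor"
  e[anchor] <- e_anchor
  rho[anchor] <- NA_real_
  material_state(density = rho, modulus = e, poisson = poisson,
                 remodels = !anchor, cal = cal)
}
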