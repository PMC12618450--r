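#' Swelling composition parameters
#'
#' A co-polymer composition is characterised by its hygroscopic swelling
#' coefficient \eqn{\beta_h} (m^3/kg) and the steady-state moisture
#' concentration change \eqn{\Delta\alpha = \alpha_m - \alpha_{m,ref}}
#' (kg/m^3) measured in free-swelling immersion experiments.  Their product
#' is the linear free-swelling strain.
#'
#' @param label Composition label, e.g. \code{"85/15"} (MMA/AA ratio).
#' @param beta_h Hygroscopic swelling coefficient, m^3/kg (non-negative).
#' @param delta_alpha Moisture concentration change, kg/m^3 (non-negative).
#' @return An object of class \code{"swelling_composition"}.
#' @export
swelling_composition <- function(label, beta_h, delta_alpha) {
  stopifnot(beta_h >= 0, delta_alpha >= 0)
  structure(list(label = label, beta_h = beta_h, delta_alpha = delta_alpha),
            class = "swelling_composition")
}

#' Registry of the three characterised MMA/AA compositions
#'
#' Free-swelling experiments in bovine serum give, per composition, the
#' swelling coefficient and steady-state moisture concentration:
#' 80/20 (beta = 1.2287 m^3/kg, dalpha = 0.1881 kg/m^3),
#' 85/15 (0.9920, 0.08672) and 90/10 (0.9032, 0.0487).
#'
#' @param label Optional composition label; if given, that single
#'   composition is returned (error with the valid labels otherwise).
#' @return A named list of \code{\link{swelling_composition}} objects, or a
#'   single composition when \code{label} is supplied.
#' @export
swelling_compositions <- function(label = NULL) {
  reg <- list(
    "80/20" = swelling_composition("80/20", 1.2287, 0.1881),
    "85/15" = swelling_composition("85/15", 0.9920, 0.08672),
    "90/10" = swelling_composition("90/10", 0.9032, 0.0487)
  )
  if (is.null(label)) return(reg)
  if (!label %in% names(reg)) {
    stop("unknown composition '", label, "'; valid labels: ",
         paste(names(reg), collapse = ", "))
  }
  reg[[label]]
}

#' Hygroscopic swelling eigenstrain
#'
#' The stress-free swelling strain is isotropic,
#' \eqn{\epsilon_{hs} = \beta_h \Delta\alpha \, s \, I}, where the
#' saturation \code{s} scales the applied moisture field (1 = fully swollen
#' steady state).  Swelling is applied as a steady-state eigenstrain, not a
#' diffusion transient: uptake completes fast relative to remodeling.
#'
#' @param comp A \code{\link{swelling_composition}}.
#' @param saturation Fraction of full saturation in [0, 1].
#' @return A 3x3 diagonal strain tensor (dimensionless).
#' @export
eigenstrain <- function(comp, saturation = 1) {
  stopifnot(inherits(comp, "swelling_composition"),
            saturation >= 0, saturation <= 1)
  diag(3) * comp$beta_h * comp$delta_alpha * saturation
}

#' Scalar linear swelling strain of a composition
#'
#' @inheritParams eigenstrain
#' @return The diagonal entry beta_h * delta_alpha * saturation.
#' @export
swelling_strain <- function(comp, saturation = 1) {
  stopifnot(saturation >= 0, saturation <= 1)
  comp$beta_h * comp$delta_alpha * saturation
}

#' Closed-form free-swelling dimensional change
#'
#' Under unconstrained isotropic linear swelling every length scales by
#' (1 + beta_h * dalpha), so the diameter and length changes of a cylinder
#' are d0 * beta * dalpha and L0 * beta * dalpha.  This closed form is what
#' a free-swelling finite element run must reproduce (patch test).
#'
#' @param diameter0,length0 Dry dimensions, mm (positive).
#' @param comp A \code{\link{swelling_composition}}.
#' @param saturation Fraction of full saturation in [0, 1].
#' @return A list with \code{d_diameter} and \code{d_length} in mm.
#' @export
free_swelling_prediction <- function(diameter0, length0, comp,
                                     saturation = 1) {
  stopifnot(diameter0 > 0, length0 > 0)
  e <- swelling_strain(comp, saturation)
  list(d_diameter = diameter0 * e, d_length = length0 * e)
}
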