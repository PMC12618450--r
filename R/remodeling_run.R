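#' Coupled finite element / remodeling iteration
#'
#' Implements the solve-update loop: a hygro-elastic FE solve gives each
#' bone element its stimulus S = U/rho; the stimulus is then frozen while
#' \code{p$resolve_every} forward-Euler density steps are taken (the rate
#' law depends on S only, so the W clamped steps collapse to one exact
#' update); each element's modulus is refreshed from its new density; and
#' the cycle repeats.  Anchor elements never remodel and keep their fixed
#' modulus.  Elements at the density floor keep the floor stiffness rather
#' than being deleted, so the mesh never changes.
#'
#' The stimulus driving the rate law is S = U/rho + \code{p$s_baseline}:
#' the baseline represents physiological background loading, so that with
#' \code{s_baseline = k} unperturbed bone sits inside the lazy zone and
#' only the swelling-induced stimulus shifts the balance (with baseline 0
#' an unloaded model is globally in disuse and drains to the floor).
#'
#' Homeostasis is declared when the maximum relative density change over a
#' trailing window of \code{p$check_horizon} checkpoints falls below
#' \code{p$convergence_tol}, or earlier when every bone element is at a
#' bound or inside the lazy zone.  The run is deterministic given its
#' inputs.
#'
#' @param mesh A \code{\link{voxel_mesh}}.
#' @param mat Initial \code{\link{material_state}}.
#' @param eig0 Per-element eigenstrain passed to
#'   \code{\link{solve_hygroelastic}} (nonzero on the anchor).
#' @param bc \code{\link{boundary_conditions}}.
#' @param p \code{\link{remodeling_params}}.
#' @param mode 2D elasticity mode, see \code{\link{solve_hygroelastic}}.
#' @param verbose Print a line per checkpoint.
#' @return A list of class \code{"remodeling_history"}: final \code{mat},
#'   final \code{state} (\code{field_state}), final \code{stimulus},
#'   per-checkpoint \code{summary} data frame, \code{converged} flag,
#'   \code{steps} (Euler steps taken), \code{initial_density}.
#' @export
run_remodeling <- function(mesh, mat, eig0, bc, p = remodeling_params(),
                           mode = "plane_stress", verbose = FALSE) {
  bone <- which(mat$remodels)
  if (length(bone) == 0) stop("no remodeling elements")
  rho0 <- mat$density
  snapshots <- vector("list", p$check_horizon)
  summ <- list()
  converged <- FALSE
  state <- NULL; S <- NULL
  hi <- (1 + p$delta) * p$k; lo <- (1 - p$delta) * p$k
  for (cp in seq_len(p$max_steps)) {
    state <- solve_hygroelastic(mesh, mat, eig0, bc, mode = mode)
    S <- stimulus_field(state, mat)
    S[bone] <- S[bone] + p$s_baseline
    rate <- density_rate(S[bone], p)
    # W Euler steps at frozen stimulus == one clamped update
    new_rho <- pmin(pmax(mat$density[bone] + p$resolve_every * p$dt * rate,
                         p$rho_min), p$rho_max)
    delta_rho <- new_rho - mat$density[bone]
    mat$density[bone] <- new_rho
    mat$modulus[bone] <- density_to_modulus(new_rho, mat$cal)
    at_floor <- new_rho <= p$rho_min + 1e-12
    at_cap <- new_rho >= p$rho_max - 1e-12
    lazy <- S[bone] >= lo & S[bone] <= hi
    summ[[cp]] <- data.frame(
      checkpoint = cp, mean_density = mean(new_rho),
      max_density = max(new_rho), min_density = min(new_rho),
      n_floor = sum(at_floor), n_cap = sum(at_cap), n_lazy = sum(lazy),
      max_rel_change = max(abs(delta_rho) / pmax(mat$density[bone], p$rho_min))
    )
    if (verbose) {
      message(sprintf("checkpoint %d: mean rho %.4f, floor %d, cap %d",
                      cp, mean(new_rho), sum(at_floor), sum(at_cap)))
    }
    # stationary: every element clamped or inside the lazy zone
    moving <- !(lazy | (at_floor & rate < 0) | (at_cap & rate > 0))
    if (!any(moving)) { converged <- TRUE }
    old <- snapshots[[1 + (cp - 1) %% p$check_horizon]]
    if (!converged && cp > p$check_horizon) {
      rel <- max(abs(new_rho - old) / pmax(old, p$rho_min))
      if (rel < p$convergence_tol) converged <- TRUE
    }
    snapshots[[1 + (cp - 1) %% p$check_horizon]] <- new_rho
    if (converged) break
  }
  structure(list(
    mat = mat, state = state, stimulus = S,
    summary = do.call(rbind, summ), converged = converged,
    steps = nrow(do.call(rbind, summ)) * p$resolve_every,
    initial_density = rho0, params = p
  ), class = "remodeling_history")
}

#' @export
print.remodeling_history <- function(x, ...) {
  n <- nrow(x$summary)
  cat("<remodeling_history> ", n, " checkpoints (",
      x$steps, " Euler steps), converged: ", x$converged, "\n", sep = "")
  cat("  bone density mean ",
      round(mean(x$initial_density[x$mat$remodels]), 4), " -> ",
      round(x$summary$mean_density[n], 4), " g/cm^3\n", sep = "")
  invisible(x)
}

#' Classify elements by their final remodeling regime
#'
#' Labels each bone element from its final density and stimulus:
#' \code{capped} / \code{floored} when a bound absorbed it, otherwise
#' \code{lazy}, \code{apposed} (stimulus above the lazy zone but below the
#' overload zero-crossing), \code{overload-resorbed} (beyond the
#' zero-crossing), or \code{disuse-resorbed} (below the lazy zone).
#'
#' @param history A \code{"remodeling_history"} from
#'   \code{\link{run_remodeling}}.
#' @param mesh The mesh of the run (for the interface/far split).
#' @param interface_dist Radial distance from the anchor surface defining
#'   the interface shell, mm (default 2, the morphometry ROI thickness).
#' @param axis_center,anchor_radius Geometry of the nominal anchor
#'   cylinder; defaults derived from the anchor elements.
#' @param axis Drill axis in 3D.
#' @return A list with per-element \code{regime} (factor), and a
#'   \code{summary} data frame of counts and mean final density by zone
#'   (interface shell vs far field).
#' @export
classify_elements <- function(history, mesh, interface_dist = 2,
                              axis_center = NULL, anchor_radius = NULL,
                              axis = 3L) {
  p <- history$params
  mat <- history$mat
  S <- history$stimulus
  hi <- (1 + p$delta) * p$k; lo <- (1 - p$delta) * p$k
  szero <- if (p$D > 0) rate_curve_landmarks(p)$S_zero else Inf
  regime <- rep(NA_character_, length(S))
  b <- mat$remodels
  rho <- mat$density
  regime[b & rho >= p$rho_max - 1e-12] <- "capped"
  regime[b & rho <= p$rho_min + 1e-12] <- "floored"
  rest <- b & is.na(regime)
  regime[rest & S >= lo & S <= hi] <- "lazy"
  regime[rest & S > hi & S <= szero] <- "apposed"
  regime[rest & S > szero] <- "overload-resorbed"
  regime[rest & S < lo] <- "disuse-resorbed"
  zone <- interface_zone(mesh, axis_center, anchor_radius, interface_dist,
                         axis)
  tab <- table(zone = zone[b], regime = regime[b])
  means <- tapply(rho[b], zone[b], mean)
  list(regime = regime,
       zone = zone,
       summary = as.data.frame.matrix(tab),
       mean_density = means)
}

# split bone elements into interface shell vs far field by radial distance
# from the nominal anchor surface
interface_zone <- function(mesh, axis_center = NULL, anchor_radius = NULL,
                           interface_dist = 2, axis = 3L) {
  nd <- mesh$nd
  plane <- if (nd == 3L) setdiff(1:3, axis) else 1:2
  anchors <- which(mesh$region == "anchor")
  if (is.null(axis_center)) {
    axis_center <- colMeans(mesh$centroid[anchors, plane, drop = FALSE])
  }
  r <- sqrt(rowSums(sweep(mesh$centroid[, plane, drop = FALSE], 2,
                          axis_center)^2))
  if (is.null(anchor_radius)) anchor_radius <- max(r[anchors]) + mesh$h / 2
  zone <- ifelse(mesh$region == "anchor", "anchor",
                 ifelse(r <= anchor_radius + interface_dist,
                        "interface", "far"))
  zone
}
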