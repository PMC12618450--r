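#' Default end-to-end run configuration
#'
#' Nested list mirroring the YAML schema accepted by
#' \code{\link{run_pipeline}}.  Every defaulted constant is echoed into the
#' run metadata for provenance.  Blocks: \code{composition} (label),
#' \code{synthetic} (2D demo image: grid, voxel size, target BVR,
#' correlation length, seed), \code{calibration}, \code{anchor} (swollen
#' modulus, Poisson ratio, saturation), \code{remodeling} (all rate-law
#' constants), \code{roi} (interface shell and far-field ROI geometry),
#' \code{mode} (elasticity mode and whether the overload term is active).
#'
#' @param composition Composition label, default \code{"85/15"}.
#' @return A named list, the default pipeline configuration.
#' @export
default_pipeline_config <- function(composition = "85/15") {
  list(
    composition = composition,
    synthetic = list(grid_n = 80L, voxel_size = 0.25, target_bvr = 0.47,
                     correlation_length = 0.6, seed = 20L,
                     hu_bone = c(200, 1000), hu_background = 0),
    geometry = list(roi_radius = 10, anchor_diameter = 8, defect_diameter = 8),
    calibration = list(density_intercept = 1041395, density_slope = 1017,
                       modulus_intercept = -388.8, modulus_slope = 5925),
    anchor = list(modulus = 75, poisson = 0.3, saturation = 1),
    marrow = list(rho0 = "hu"),
    remodeling = list(B = 1.0, D = 60, k = 0.004, delta = 0.10, dt = 0.01,
                      rho_min = 0.01, rho_max = 2.0, s_baseline = 0.004,
                      convergence_tol = 0.02,
                      resolve_every = 100L, check_horizon = 10L,
                      max_steps = 600L),
    roi = list(interface_thickness = 2, far_offset = c(-5.657, -5.657)),
    pushout = list(mu = 0.4),
    mode = list(elasticity = "plane_stress", overload = TRUE)
  )
}

#' Read a pipeline configuration from YAML
#'
#' Unknown keys (at the top level or inside a block) are rejected;
#' omitted keys take their defaults.
#'
#' @param path YAML file path.
#' @return A validated configuration list.
#' @export
read_pipeline_config <- function(path) {
  user <- yaml::read_yaml(path)
  merge_config(user)
}

merge_config <- function(user) {
  base <- default_pipeline_config()
  if (is.null(user)) return(base)
  bad <- setdiff(names(user), names(base))
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  for (nm in names(user)) {
    if (is.list(base[[nm]]) && is.list(user[[nm]])) {
      badk <- setdiff(names(user[[nm]]), names(base[[nm]]))
      if (length(badk)) {
        stop("unknown config keys in '", nm, "': ",
             paste(badk, collapse = ", "))
      }
      base[[nm]][names(user[[nm]])] <- user[[nm]]
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

#' Build the packaged 2D demo model
#'
#' A synthetic trabecular disc: a 2D HU image is generated, the press-fit
#' defect is drilled at the center, voxels outside the circular region of
#' interest are excluded, and the remaining voxels are meshed with
#' HU-calibrated heterogeneous properties (marrow included, as in the
#' gap-filled workflow).  The outer rim of the disc is fully fixed
#' (\code{constrained_lateral}); the anchor carries the composition's
#' swelling eigenstrain.
#'
#' @param config Configuration list, see
#'   \code{\link{default_pipeline_config}}.
#' @return A list with \code{image}, \code{labels}, \code{mesh},
#'   \code{mat}, \code{eig0}, \code{bc}, \code{facets}, \code{comp},
#'   \code{center}, and the config used.
#' @export
build_demo_model <- function(config = default_pipeline_config()) {
  config <- merge_config(config)
  syn <- config$synthetic
  geo <- config$geometry
  comp <- swelling_compositions(config$composition)
  cal <- do.call(calibration_constants, config$calibration)
  img <- generate_trabecular_image(
    shape = c(syn$grid_n, syn$grid_n), voxel_size = syn$voxel_size,
    target_bvr = syn$target_bvr,
    correlation_length = syn$correlation_length,
    hu_bone = syn$hu_bone, hu_background = syn$hu_background,
    seed = syn$seed)
  side <- syn$grid_n * syn$voxel_size
  center <- c(side / 2, side / 2)
  drilled <- drill_and_insert(img, defect_spec(
    center, diameter = geo$defect_diameter,
    anchor_diameter = geo$anchor_diameter))
  labels <- drilled$labels
  d <- dim(labels)
  cx <- voxel_centers(d[1], syn$voxel_size, img$origin[1])
  cy <- voxel_centers(d[2], syn$voxel_size, img$origin[2])
  r <- sqrt(outer((cx - center[1])^2, (cy - center[2])^2, `+`))
  labels[r >= geo$roi_radius] <- "outside"
  mesh <- voxel_mesh(labels, syn$voxel_size, img$origin)
  hu_elem <- drilled$image$values[mesh$voxel_index]
  rho_marrow <- if (identical(config$marrow$rho0, "hu")) NULL else
    config$marrow$rho0
  mat <- material_from_hu(hu_elem, mesh$region,
                          e_anchor = config$anchor$modulus,
                          poisson = config$anchor$poisson,
                          rho_marrow = rho_marrow, cal = cal)
  eig0 <- ifelse(mesh$region == "anchor",
                 swelling_strain(comp, config$anchor$saturation), 0)
  rim <- geo$roi_radius - 1.01 * syn$voxel_size
  bc <- bc_fix_where(mesh, function(nodes) {
    sqrt((nodes[, 1] - center[1])^2 + (nodes[, 2] - center[2])^2) >= rim
  }, tag = "constrained_lateral")
  facets <- interface_facets(mesh, axis_center = center)
  list(image = drilled$image, labels = labels, mesh = mesh, mat = mat,
       eig0 = eig0, bc = bc, facets = facets, comp = comp,
       center = center, config = config)
}

#' Run the full analysis pipeline
#'
#' generate -> calibrate -> swell/solve -> remodel -> morphometry ->
#' push-out, writing VTK fields, CSV tables, a text report, and a JSON
#' metadata echo of every parameter and seed to \code{out_dir}.  Reruns
#' with the same configuration are bit-identical.
#'
#' @param config Configuration list or YAML path.
#' @param out_dir Output directory (created); \code{NULL} skips all file
#'   output and returns results only.
#' @param verbose Print stage progress.
#' @return A list with the model, remodeling history, element
#'   classification, interface/far BVR results, and the push-out
#'   comparison.
#' @export
run_pipeline <- function(config = default_pipeline_config(),
                         out_dir = NULL, verbose = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  config <- merge_config(config)
  say <- function(...) if (verbose) message(format(Sys.time(), "%H:%M:%S "),
                                            ...)
  say("stage generate: building demo model (", config$composition, ")")
  model <- build_demo_model(config)
  rem <- config$remodeling
  if (!isTRUE(config$mode$overload)) rem$D <- 0
  p <- do.call(remodeling_params, rem)
  say("stage solve+remodel: iterating to homeostasis")
  pre_state <- solve_hygroelastic(model$mesh, model$mat, model$eig0,
                                  model$bc,
                                  mode = config$mode$elasticity)
  hist <- run_remodeling(model$mesh, model$mat, model$eig0, model$bc, p,
                         mode = config$mode$elasticity)
  say("stage classify")
  cls <- classify_elements(hist, model$mesh,
                           interface_dist = config$roi$interface_thickness,
                           axis_center = model$center,
                           anchor_radius = config$geometry$anchor_diameter / 2)
  say("stage morphometry: BVR on the projected HU field")
  proj <- density_to_hu_projection(hist$mat, model$mesh)
  ring <- hollow_cylinder_mask(
    proj, model$center,
    inner_radius = config$geometry$anchor_diameter / 2,
    thickness = config$roi$interface_thickness)
  far_center <- model$center + config$roi$far_offset
  # the equal-volume far disc cannot always both avoid the interface shell
  # and stay inside the 2D demo domain; cap its volume to what fits
  d_axis <- sqrt(sum(config$roi$far_offset^2))
  shell_outer <- config$geometry$anchor_diameter / 2 +
    config$roi$interface_thickness
  r_fit <- min(d_axis - shell_outer, config$geometry$roi_radius - d_axis)
  if (r_fit <= proj$voxel_size) {
    stop("far-field ROI does not fit between the interface shell and the ",
         "domain edge; adjust roi$far_offset")
  }
  v0_far <- min(ring$v0, pi * r_fit^2 * (1 - 1e-9))
  far <- equal_volume_sphere_mask(proj, far_center, v0_far)
  bvr_interface <- bone_volume_ratio(proj, ring, label = "interface")
  bvr_far <- bone_volume_ratio(proj, far, label = "far")
  say("stage pushout")
  pre <- pushout_estimate(pre_state, model$mesh, model$facets,
                          mu = config$pushout$mu)
  post <- pushout_estimate(hist$state, model$mesh, model$facets,
                           mu = config$pushout$mu)
  fix <- compare_fixation(pre, post)
  res <- list(model = model, pre_state = pre_state, history = hist,
              classification = cls,
              bvr = list(interface = bvr_interface, far = bvr_far),
              pushout = fix, config = config)
  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  res
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  mesh <- res$model$mesh
  hist <- res$history
  region_code <- as.numeric(factor(mesh$region, c("bone", "anchor")))
  write_vtk(mesh, file.path(out_dir, "final_fields.vtk"),
            point_vectors = list(displacement = hist$state$u),
            cell_scalars = list(density = replace_na(hist$mat$density, -1),
                                sed = hist$state$sed,
                                stimulus = hist$stimulus,
                                region = region_code))
  utils::write.csv(hist$summary,
                   file.path(out_dir, "remodeling_checkpoints.csv"),
                   row.names = FALSE)
  b <- hist$mat$remodels
  elems <- data.frame(element = which(b),
                      density_initial = hist$initial_density[b],
                      density_final = hist$mat$density[b],
                      stimulus = hist$stimulus[b],
                      regime = res$classification$regime[b],
                      zone = res$classification$zone[b])
  utils::write.csv(elems, file.path(out_dir, "element_table.csv"),
                   row.names = FALSE)
  cfg_json <- jsonlite::toJSON(res$config, auto_unbox = TRUE, digits = NA)
  meta <- list(config = res$config,
               config_hash = config_hash(res$config),
               converged = hist$converged, checkpoints = nrow(hist$summary))
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE),
             file.path(out_dir, "metadata.json"))
  rep <- c(
    paste0("composition: ", res$config$composition),
    paste0("config hash: ", config_hash(res$config)),
    paste0("converged: ", hist$converged, " after ",
           nrow(hist$summary), " checkpoints (", hist$steps,
           " Euler steps)"),
    paste0("mean interface density: ",
           round(mean(hist$initial_density[b &
             res$classification$zone == "interface"]), 4), " -> ",
           round(res$classification$mean_density[["interface"]], 4),
           " g/cm^3"),
    paste0("interface BVR ", round(res$bvr$interface$ratio, 4),
           " vs far-field BVR ", round(res$bvr$far$ratio, 4)),
    paste0("push-out force ", round(res$pushout$f_pre, 3), " -> ",
           round(res$pushout$f_post, 3), " N/mm (",
           sprintf("%+.1f%%", 100 * res$pushout$relative_change), ")"),
    "regime counts by zone:",
    utils::capture.output(print(res$classification$summary))
  )
  writeLines(rep, file.path(out_dir, "report.txt"))
  invisible(out_dir)
}

replace_na <- function(x, v) { x[is.na(x)] <- v; x }

# deterministic short hash of a configuration (serialized canonical JSON)
config_hash <- function(config) {
  js <- as.character(jsonlite::toJSON(config, auto_unbox = TRUE,
                                      digits = NA))
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeChar(js, tmp, eos = NULL)
  substr(unname(tools::md5sum(tmp)), 1, 8)
}

#' Free-swelling validation table
#'
#' For each composition, runs an unconstrained 3D finite element swelling
#' of an anchor-sized block and compares the diameter and length change
#' with the closed form d0 * beta * dalpha (patch test: the relative error
#' must vanish to solver precision).
#'
#' @param compositions List of \code{\link{swelling_composition}}s;
#'   default: the full registry.
#' @param diameter,length0 Anchor dimensions, mm (default 8 and 8).
#' @param n Elements per edge of the block (patch-exact at any n).
#' @param e_anchor,poisson Anchor elastic properties.
#' @return A data frame with FE and closed-form dimensional changes and
#'   their relative error, one row per composition.
#' @export
run_free_swelling <- function(compositions = swelling_compositions(),
                              diameter = 8, length0 = 8, n = 4,
                              e_anchor = 50, poisson = 0.3) {
  h <- diameter / n
  labels <- array("anchor", dim = c(n, n, max(1L, round(length0 / h))))
  mesh <- voxel_mesh(labels, h, region_map = c(anchor = "anchor"))
  nelem <- nrow(mesh$elem)
  mat <- material_state(density = rep(NA_real_, nelem),
                        modulus = rep(e_anchor, nelem), poisson = poisson,
                        remodels = rep(FALSE, nelem))
  bc <- bc_free_swelling(mesh)
  rows <- lapply(compositions, function(comp) {
    e0 <- swelling_strain(comp)
    st <- solve_hygroelastic(mesh, mat, e0, bc)
    dx <- range(mesh$nodes[, 1])
    dz <- range(mesh$nodes[, 3])
    right <- mesh$nodes[, 1] == dx[2]; left <- mesh$nodes[, 1] == dx[1]
    top <- mesh$nodes[, 3] == dz[2]; bot <- mesh$nodes[, 3] == dz[1]
    d_d <- mean(st$u[right, 1]) - mean(st$u[left, 1])
    d_l <- mean(st$u[top, 3]) - mean(st$u[bot, 3])
    pred <- free_swelling_prediction(diameter, length0, comp)
    data.frame(composition = comp$label,
               fe_d_diameter = d_d, closed_d_diameter = pred$d_diameter,
               fe_d_length = d_l, closed_d_length = pred$d_length,
               rel_err_diameter = if (pred$d_diameter > 0) {
                 abs(d_d - pred$d_diameter) / pred$d_diameter
               } else abs(d_d),
               rel_err_length = if (pred$d_length > 0) {
                 abs(d_l - pred$d_length) / pred$d_length
               } else abs(d_l))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
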