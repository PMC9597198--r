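# End-to-end orchestration: design -> mesh -> suture -> release -> report.

#' Simulation configuration
#'
#' All defaults reproduce the reference operative scenario: a 10 mm defect
#' closed with a 60 degree apex A-T flap in a 90 x 100 mm skin region,
#' meshed at 3 mm (the clinical suture-bite-stitch interval is 2-5 mm),
#' with the two-term facial-skin Ogden material.
#'
#' @param radius Defect radius in mm.
#' @param apex Apex angle in degrees, in (10, 170).
#' @param width,height Domain size in mm.
#' @param element_size Element side length in mm.
#' @param base_extension_factor Base incision length multiple of the defect
#'   diameter.
#' @param target_strategy Suture target mapping passed to
#'   [generate_mesh()] (`"isometric"` default).
#' @param material An [ogden_parameters()] object.
#' @param solver A [solver_config()].
#' @param out_dir Optional output directory for artifacts.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(radius = 10, apex = 60, width = 90,
                              height = 100, element_size = 3,
                              base_extension_factor = 3,
                              target_strategy = "isometric",
                              material = facial_skin_ogden(),
                              solver = solver_config(), out_dir = NULL) {
  stopifnot(radius > 0, width > 0, height > 0, element_size > 0)
  if (apex <= 10 || apex >= 170) {
    stop("apex angle must lie in (10, 170) degrees", call. = FALSE)
  }
  structure(list(radius = radius, apex = apex, width = width,
                 height = height, element_size = element_size,
                 base_extension_factor = base_extension_factor,
                 target_strategy = target_strategy,
                 material = material, solver = solver, out_dir = out_dir),
            class = "simulation_config")
}

#' Write / read a simulation configuration
#'
#' Human-editable YAML; round-trips to an equal configuration.
#'
#' @param config A [simulation_config()].
#' @param path YAML file path.
#' @return `read_sim_config`: a `simulation_config`.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "simulation_config"))
  obj <- list(
    radius = config$radius, apex = config$apex,
    width = config$width, height = config$height,
    element_size = config$element_size,
    base_extension_factor = config$base_extension_factor,
    target_strategy = config$target_strategy,
    material = list(mu = sprintf("%.17g", config$material$mu),
                    alpha = sprintf("%.17g", config$material$alpha)),
    solver = unclass(config$solver))
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  obj <- yaml::read_yaml(path)
  simulation_config(
    radius = obj$radius, apex = obj$apex, width = obj$width,
    height = obj$height, element_size = obj$element_size,
    base_extension_factor = obj$base_extension_factor,
    target_strategy = obj$target_strategy,
    material = ogden_parameters(mu = as.numeric(obj$material$mu),
                                alpha = as.numeric(obj$material$alpha)),
    solver = do.call(solver_config, obj$solver))
}

#' Run the full preoperative evaluation pipeline
#'
#' Designs the flap, builds the domain and mesh, solves the suture and
#' release stages, and summarizes the results.  When `config$out_dir` is
#' set, writes the artifacts: mesh VTK, per-stage field VTK and nodal CSV,
#' quality report CSV, summary JSON and a copy of the configuration.
#' Deterministic for a fixed configuration.
#'
#' @param config A [simulation_config()].
#' @param quiet Suppress progress messages (default TRUE).
#' @return An object of class `run_report`: design, mesh summary and
#'   quality report, per-stage maxima with node locations, convergence
#'   diagnostics and the two `field_solution` objects (`solutions`).
#' @export
run_pipeline <- function(config, quiet = TRUE) {
  stopifnot(inherits(config, "simulation_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  t0 <- proc.time()[["elapsed"]]
  design <- design_flap(config$radius, config$apex,
                        config$base_extension_factor)
  domain <- build_domain(design, config$width, config$height)
  mesh <- generate_mesh(domain, config$element_size, config$target_strategy)
  quality <- quality_report(mesh)
  say("mesh: %d elements, %d nodes", quality$n_elements, quality$n_nodes)
  sols <- run_suture_then_release(mesh, config$material, config$solver)
  say("suture : max vM %.3f MPa, max |u| %.3f mm",
      sols$suture$max_vm, sols$suture$max_disp)
  say("release: max vM %.3f MPa, max |u| %.3f mm",
      sols$release$max_vm, sols$release$max_disp)
  stage_summary <- function(sol) {
    list(max_von_mises_mpa = sol$max_vm,
         max_von_mises_node = sol$max_vm_node,
         max_von_mises_at = as.numeric(mesh$nodes[sol$max_vm_node, ]),
         max_displacement_mm = sol$max_disp,
         max_displacement_node = sol$max_disp_node,
         max_displacement_at = as.numeric(mesh$nodes[sol$max_disp_node, ]),
         converged = sol$converged,
         newton_iterations = sum(vapply(sol$residual_history,
                                        function(h) h$iters, numeric(1))),
         load_steps = length(sol$residual_history))
  }
  report <- structure(list(
    design = list(r = design$r, apex_deg = design$apex_deg, h = design$h,
                  d = design$d, ratio = design$ratio, S = design$S),
    mesh = as.data.frame(quality),
    suture = stage_summary(sols$suture),
    release = stage_summary(sols$release),
    elapsed_s = proc.time()[["elapsed"]] - t0,
    solutions = sols,
    mesh_object = mesh,
    config = config,
    manifest = character(0)
  ), class = "run_report")
  if (!is.null(config$out_dir)) {
    report$manifest <- write_run_artifacts(report, config$out_dir)
  }
  report
}

write_run_artifacts <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  mesh <- report$mesh_object
  paths <- c(
    mesh_vtk = file.path(out_dir, "mesh.vtk"),
    suture_vtk = file.path(out_dir, "suture.vtk"),
    release_vtk = file.path(out_dir, "release.vtk"),
    suture_csv = file.path(out_dir, "suture_nodal.csv"),
    release_csv = file.path(out_dir, "release_nodal.csv"),
    quality_csv = file.path(out_dir, "mesh_quality.csv"),
    summary_json = file.path(out_dir, "summary.json"),
    config_yaml = file.path(out_dir, "config.yaml"))
  write_vtk_mesh(mesh, paths[["mesh_vtk"]])
  write_vtk_fields(mesh, report$solutions$suture, paths[["suture_vtk"]])
  write_vtk_fields(mesh, report$solutions$release, paths[["release_vtk"]])
  write_nodal_csv(mesh, report$solutions$suture, paths[["suture_csv"]])
  write_nodal_csv(mesh, report$solutions$release, paths[["release_csv"]])
  utils::write.csv(report$mesh, paths[["quality_csv"]], row.names = FALSE)
  summary_obj <- report[c("design", "mesh", "suture", "release", "elapsed_s")]
  jsonlite::write_json(summary_obj, paths[["summary_json"]],
                       auto_unbox = TRUE, digits = NA)
  write_sim_config(report$config, paths[["config_yaml"]])
  paths
}

#' @export
print.run_report <- function(x, ...) {
  cat("A-T flap simulation report\n")
  cat(sprintf("  design : r = %g mm, apex = %g deg, h = %.2f mm, d = %.2f mm, S = %.1f mm^2\n",
              x$design$r, x$design$apex_deg, x$design$h, x$design$d, x$design$S))
  cat(sprintf("  mesh   : %d elements, %d nodes (%d inverted, %d distorted, %d bad aspect)\n",
              x$mesh$n_elements, x$mesh$n_nodes, x$mesh$n_inverted,
              x$mesh$n_distorted, x$mesh$n_bad_aspect))
  for (stg in c("suture", "release")) {
    s <- x[[stg]]
    cat(sprintf("  %-7s: max vM %.3f MPa at (%.1f, %.1f), max |u| %.3f mm at (%.1f, %.1f)\n",
                stg, s$max_von_mises_mpa, s$max_von_mises_at[1],
                s$max_von_mises_at[2], s$max_displacement_mm,
                s$max_displacement_at[1], s$max_displacement_at[2]))
  }
  cat(sprintf("  elapsed: %.1f s\n", x$elapsed_s))
  invisible(x)
}

#' Mesh-sensitivity study
#'
#' Re-runs the full two-stage simulation at several element sizes and
#' tabulates element/node counts, the mesh-quality triple and the
#' release-stage maxima — the usual element-size sensitivity table.
#'
#' @param config A [simulation_config()] (its `element_size` is ignored).
#' @param sizes Numeric vector of element sizes in mm (>= 2 values for a
#'   study; a single size yields a single row).
#' @param quiet Suppress progress messages.
#' @return A `data.frame` with one row per size: `element_size`,
#'   `n_elements`, `n_nodes`, `max_vm_release_mpa`, `max_disp_release_mm`,
#'   `max_vm_suture_mpa`, `max_disp_suture_mm`, `n_inverted`,
#'   `n_distorted`, `n_bad_aspect`.
#' @export
mesh_sensitivity_study <- function(config, sizes = c(4, 3, 2, 1),
                                   quiet = TRUE) {
  stopifnot(length(sizes) >= 1)
  rows <- lapply(sizes, function(sz) {
    cfg <- config
    cfg$element_size <- sz
    cfg$out_dir <- NULL
    rep_i <- run_pipeline(cfg, quiet = quiet)
    data.frame(element_size = sz,
               n_elements = rep_i$mesh$n_elements,
               n_nodes = rep_i$mesh$n_nodes,
               max_vm_release_mpa = rep_i$release$max_von_mises_mpa,
               max_disp_release_mm = rep_i$release$max_displacement_mm,
               max_vm_suture_mpa = rep_i$suture$max_von_mises_mpa,
               max_disp_suture_mm = rep_i$suture$max_displacement_mm,
               n_inverted = rep_i$mesh$n_inverted,
               n_distorted = rep_i$mesh$n_distorted,
               n_bad_aspect = rep_i$mesh$n_bad_aspect)
  })
  do.call(rbind, rows)
}
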