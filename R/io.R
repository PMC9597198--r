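# Mesh and field export in standard text formats.

#' Write a mesh as legacy ASCII VTK
#'
#' Unstructured grid of VTK quads (cell type 9); 2-D coordinates are padded
#' with z = 0.
#'
#' @param mesh A `skin_mesh`.
#' @param path Output `.vtk` path.
#' @return `path`, invisibly.
#' @export
write_vtk_mesh <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  n <- nrow(mesh$nodes)
  m <- nrow(mesh$elems)
  writeLines(c("# vtk DataFile Version 3.0",
               "atflap skin mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", n)), con)
  writeLines(sprintf("%.9g %.9g 0", mesh$nodes[, 1], mesh$nodes[, 2]), con)
  writeLines(sprintf("CELLS %d %d", m, 5L * m), con)
  writeLines(sprintf("4 %d %d %d %d",
                     mesh$elems[, 1] - 1L, mesh$elems[, 2] - 1L,
                     mesh$elems[, 3] - 1L, mesh$elems[, 4] - 1L), con)
  writeLines(sprintf("CELL_TYPES %d", m), con)
  writeLines(rep("9", m), con)
  invisible(path)
}

#' Write a field solution as legacy ASCII VTK
#'
#' The mesh plus point data: the displacement vector field and the
#' nodal-averaged von Mises scalar.
#'
#' @param mesh A `skin_mesh`.
#' @param solution A `field_solution` from [solve_stage()].
#' @param path Output `.vtk` path.
#' @return `path`, invisibly.
#' @export
write_vtk_fields <- function(mesh, solution, path) {
  write_vtk_mesh(mesh, path)
  con <- file(path, "a")
  on.exit(close(con))
  n <- nrow(mesh$nodes)
  writeLines(sprintf("POINT_DATA %d", n), con)
  writeLines("VECTORS displacement double", con)
  writeLines(sprintf("%.9g %.9g 0", solution$u[, 1], solution$u[, 2]), con)
  writeLines(c("SCALARS von_mises double 1", "LOOKUP_TABLE default"), con)
  writeLines(sprintf("%.9g", solution$nodal_vm), con)
  invisible(path)
}

#' Write a mesh in Gmsh MSH 2.2 ASCII format
#'
#' @param mesh A `skin_mesh`.
#' @param path Output `.msh` path.
#' @return `path`, invisibly.
#' @export
write_msh_mesh <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  n <- nrow(mesh$nodes)
  m <- nrow(mesh$elems)
  writeLines(c("$MeshFormat", "2.2 0 8", "$EndMeshFormat", "$Nodes",
               sprintf("%d", n)), con)
  writeLines(sprintf("%d %.9g %.9g 0", seq_len(n),
                     mesh$nodes[, 1], mesh$nodes[, 2]), con)
  writeLines(c("$EndNodes", "$Elements", sprintf("%d", m)), con)
  reg <- as.integer(factor(mesh$region))
  writeLines(sprintf("%d 3 2 %d %d %d %d %d %d", seq_len(m), reg, reg,
                     mesh$elems[, 1], mesh$elems[, 2],
                     mesh$elems[, 3], mesh$elems[, 4]), con)
  writeLines("$EndElements", con)
  invisible(path)
}

#' Write nodal results as CSV
#'
#' Columns: node, reference coordinates, displacements, averaged stress
#' components and von Mises.
#'
#' @param mesh A `skin_mesh`.
#' @param solution A `field_solution`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_nodal_csv <- function(mesh, solution, path) {
  df <- data.frame(node = seq_len(nrow(mesh$nodes)),
                   x_mm = mesh$nodes[, 1], y_mm = mesh$nodes[, 2],
                   ux_mm = solution$u[, 1], uy_mm = solution$u[, 2],
                   s11_mpa = solution$nodal_stress[, 1],
                   s22_mpa = solution$nodal_stress[, 2],
                   s12_mpa = solution$nodal_stress[, 3],
                   von_mises_mpa = solution$nodal_vm)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
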