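#' Write mesh and fields as a legacy ASCII VTK unstructured grid
#'
#' Point data are per-node vectors (e.g. displacement); cell data are
#' per-element scalars (density, SED, stimulus, region code).  Legacy VTK
#' is plain text and readable by ParaView and VisIt.
#'
#' @param mesh A \code{\link{voxel_mesh}}.
#' @param path Output file path (.vtk).
#' @param point_vectors Named list of n_node x nd matrices.
#' @param cell_scalars Named list of per-element numeric vectors.
#' @return Invisibly, \code{path}.
#' @export
write_vtk <- function(mesh, path, point_vectors = list(),
                      cell_scalars = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  nd <- mesh$nd
  nn <- nrow(mesh$nodes)
  ne <- nrow(mesh$elem)
  nne <- ncol(mesh$elem)
  pts <- mesh$nodes
  if (nd == 2L) pts <- cbind(pts, 0)
  writeLines(c("# vtk DataFile Version 3.0",
               "hygrobone field output", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               paste("POINTS", nn, "double")), con)
  utils::write.table(format(pts, scientific = TRUE, digits = 9), con,
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  writeLines(paste("CELLS", ne, ne * (nne + 1)), con)
  utils::write.table(cbind(nne, mesh$elem - 1L), con, quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  writeLines(paste("CELL_TYPES", ne), con)
  writeLines(as.character(rep(if (nd == 2L) 9L else 12L, ne)), con)
  if (length(point_vectors)) {
    writeLines(paste("POINT_DATA", nn), con)
    for (nm in names(point_vectors)) {
      v <- point_vectors[[nm]]
      if (ncol(v) == 2L) v <- cbind(v, 0)
      writeLines(paste("VECTORS", nm, "double"), con)
      utils::write.table(format(v, scientific = TRUE, digits = 9), con,
                         quote = FALSE, row.names = FALSE,
                         col.names = FALSE)
    }
  }
  if (length(cell_scalars)) {
    writeLines(paste("CELL_DATA", ne), con)
    for (nm in names(cell_scalars)) {
      writeLines(c(paste("SCALARS", nm, "double", 1),
                   "LOOKUP_TABLE default"), con)
      writeLines(format(cell_scalars[[nm]], scientific = TRUE, digits = 9),
                 con)
    }
  }
  invisible(path)
}
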