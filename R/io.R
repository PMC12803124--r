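# Text-based artifact I/O: PLY and CSV point clouds, ASCII VTU meshes,
# JSON atlas containers and cohort manifests.

#' Write a surface cloud as ASCII PLY
#'
#' Ordered vertices with a per-vertex integer label scalar.
#'
#' @param cloud a `surface_cloud`.
#' @param path output file.
#' @export
write_cloud_ply <- function(cloud, path) {
  n <- nrow(cloud$points)
  hdr <- c("ply", "format ascii 1.0",
           sprintf("comment frame %s", cloud$frame),
           sprintf("element vertex %d", n),
           "property float x", "property float y", "property float z",
           "property int label", "end_header")
  body <- sprintf("%.6f %.6f %.6f %d", cloud$points[, 1], cloud$points[, 2],
                  cloud$points[, 3], as.integer(cloud$labels))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write a surface cloud as CSV (x, y, z, label, frame)
#' @param cloud a `surface_cloud`.
#' @param path output file.
#' @export
write_cloud_csv <- function(cloud, path) {
  df <- data.frame(x = cloud$points[, 1], y = cloud$points[, 2],
                   z = cloud$points[, 3], label = as.character(cloud$labels),
                   frame = cloud$frame)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a tagged tetrahedral mesh as ASCII VTU
#'
#' Optional nodal (`point_data`) and per-element (`cell_data`) scalar or
#' vector fields are written as data arrays.
#'
#' @param mesh a `tet_mesh`.
#' @param path output file.
#' @param point_data named list of per-node vectors/matrices.
#' @param cell_data named list of per-element vectors/matrices.
#' @export
write_mesh_vtu <- function(mesh, path, point_data = list(), cell_data = list()) {
  nv <- nrow(mesh$nodes); nt <- nrow(mesh$tets)
  num <- function(x) paste(format(x, trim = TRUE, digits = 9), collapse = " ")
  da <- function(name, m) {
    m <- as.matrix(m)
    sprintf('<DataArray type="Float64" Name="%s" NumberOfComponents="%d" format="ascii">\n%s\n</DataArray>',
            name, ncol(m), num(t(m)))
  }
  lines <- c('<?xml version="1.0"?>',
             '<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">',
             '<UnstructuredGrid>',
             sprintf('<Piece NumberOfPoints="%d" NumberOfCells="%d">', nv, nt),
             '<Points>', da("Points", mesh$nodes), '</Points>',
             '<Cells>',
             sprintf('<DataArray type="Int32" Name="connectivity" format="ascii">\n%s\n</DataArray>',
                     num(t(mesh$tets) - 1L)),
             sprintf('<DataArray type="Int32" Name="offsets" format="ascii">\n%s\n</DataArray>',
                     num(seq_len(nt) * 4L)),
             sprintf('<DataArray type="UInt8" Name="types" format="ascii">\n%s\n</DataArray>',
                     num(rep(10L, nt))),
             '</Cells>')
  if (length(point_data)) {
    lines <- c(lines, '<PointData>',
               unlist(lapply(names(point_data), function(nm) da(nm, point_data[[nm]]))),
               '</PointData>')
  }
  if (length(cell_data)) {
    lines <- c(lines, '<CellData>',
               unlist(lapply(names(cell_data), function(nm) da(nm, cell_data[[nm]]))),
               '</CellData>')
  }
  lines <- c(lines, '</Piece>', '</UnstructuredGrid>', '</VTKFile>')
  writeLines(lines, path)
  invisible(path)
}

#' Serialize a shape atlas to a JSON container
#'
#' Mean, modes, explained variances, labels and layout metadata in one
#' self-contained file; [read_atlas_json()] restores it.
#'
#' @param atlas a `shape_atlas`.
#' @param path output file.
#' @export
write_atlas_json <- function(atlas, path) {
  spec <- atlas$reference$spec
  obj <- list(n_points = atlas$n_points,
              mean = atlas$mean,
              modes = atlas$modes,
              explained_variance = atlas$explained_variance,
              labels = as.character(atlas$labels),
              frame = atlas$reference$frame,
              resolution = unclass(spec$resolution),
              axes = spec$axes, ring_axes = spec$ring_axes,
              z_base = spec$z_base, z_apex = as.list(spec$z_apex),
              reference_points = atlas$reference$points)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Restore a shape atlas from its JSON container
#' @param path file written by [write_atlas_json()].
#' @return a `shape_atlas`.
#' @export
read_atlas_json <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  res <- atlas_resolution(o$resolution$LV_ENDO, o$resolution$EPI,
                          o$resolution$RV_ENDO, o$resolution$n_ring)
  spec <- list(resolution = res, layout = cloud_layout(res),
               axes = lapply(o$axes, as.numeric),
               ring_axes = lapply(o$ring_axes, as.numeric),
               z_base = o$z_base, z_apex = unlist(o$z_apex))
  labels <- factor(o$labels, levels = ALL_LABELS)
  reference <- new_surface_cloud(as.matrix(o$reference_points), labels,
                                 o$frame, spec)
  structure(list(mean = as.numeric(o$mean), modes = as.matrix(o$modes),
                 explained_variance = as.numeric(o$explained_variance),
                 n_points = o$n_points, labels = labels,
                 reference = reference),
            class = "shape_atlas")
}

#' Write a cohort manifest (scores, hemodynamics, unloading reports)
#'
#' @param scores named list of PC score vectors.
#' @param unloading optional named list of `unloading_result`s.
#' @param path output file.
#' @export
write_cohort_manifest <- function(scores, unloading = NULL, path) {
  cases <- lapply(names(scores), function(gid) {
    entry <- list(geometry_id = gid, scores = scores[[gid]])
    if (!is.null(unloading[[gid]])) {
      u <- unloading[[gid]]
      entry$unloading <- list(v0_target = u$v0_target,
                              v0_achieved = u$v0_achieved,
                              iterations = u$iterations,
                              converged = u$converged,
                              lambda = u$lambda)
    }
    entry
  })
  jsonlite::write_json(cases, path, digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
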