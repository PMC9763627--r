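#' Write / read a trajectory table
#'
#' CSV with a fixed header contract (`time, displacement, f_ot, f_agg_x,
#' contact_area, overlap, n_ave, area1, vol1, area2, vol2, amount1,
#' amount2, min_sep, n_contact, f_fric_x`); a round-trip reproduces the
#' values to full double precision.
#'
#' @param traj a `cbmm_trajectory` (or plain data.frame with the columns).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  df <- as.data.frame(traj)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(names(df), collapse = ","), con)
  body <- do.call(paste, c(lapply(df, function(col)
    formatC(col, digits = 17, format = "g")), sep = ","))
  writeLines(body, con)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  structure(df, class = c("cbmm_trajectory", "data.frame"))
}

#' Write a mesh snapshot in legacy VTK PolyData format
#'
#' ASCII legacy VTK readable by standard viewers, carrying optional
#' per-vertex scalar fields (e.g. the mobile-Fg density `n_mfg`, the gap
#' distance `r_vts`) and vector fields (velocity, adhesion force).
#'
#' @param mesh a [tri_mesh()].
#' @param path output `.vtk` file.
#' @param vertices optional deformed positions.
#' @param scalars named list of length-n numeric vectors.
#' @param vectors named list of n x 3 matrices.
#' @return `path`, invisibly.
#' @export
write_snapshot_vtk <- function(mesh, path, vertices = mesh$vertex_positions,
                               scalars = list(), vectors = list()) {
  nv <- nrow(vertices)
  nt <- nrow(mesh$triangles)
  con <- file(path, "w")
  on.exit(close(con))
  num <- function(x) formatC(x, digits = 17, format = "g")
  writeLines(c("# vtk DataFile Version 3.0",
               "rbcbridge snapshot", "ASCII",
               "DATASET POLYDATA",
               paste("POINTS", nv, "double")), con)
  writeLines(paste(num(vertices[, 1]), num(vertices[, 2]),
                   num(vertices[, 3])), con)
  writeLines(paste("POLYGONS", nt, 4 * nt), con)
  writeLines(paste(3, mesh$triangles[, 1] - 1L, mesh$triangles[, 2] - 1L,
                   mesh$triangles[, 3] - 1L), con)
  if (length(scalars) || length(vectors)) {
    writeLines(paste("POINT_DATA", nv), con)
    for (nm in names(scalars)) {
      writeLines(c(paste("SCALARS", nm, "double 1"),
                   "LOOKUP_TABLE default"), con)
      writeLines(num(scalars[[nm]]), con)
    }
    for (nm in names(vectors)) {
      v <- vectors[[nm]]
      writeLines(paste("VECTORS", nm, "double"), con)
      writeLines(paste(num(v[, 1]), num(v[, 2]), num(v[, 3])), con)
    }
  }
  invisible(path)
}

#' Write the JSON run manifest
#'
#' Echoes every resolved parameter in SI units plus run metadata, so a run
#' is fully reproducible from its manifest.
#'
#' @param params named list (e.g. the `params` attribute of a trajectory,
#'   or a [cbmm_preset()]).
#' @param path output `.json` file.
#' @param extra optional named list of extra metadata (seed, wall time...).
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(params, path, extra = list()) {
  strip <- function(x) {
    if (is.list(x)) lapply(unclass(x), strip) else x
  }
  payload <- c(list(package = "rbcbridge",
                    version = as.character(utils::packageVersion("rbcbridge")),
                    created = format(Sys.time(), tz = "UTC")),
               strip(params), extra)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
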