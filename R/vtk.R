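# Minimal legacy-ASCII VTK polydata I/O for meshes, point clouds and their
# scalar fields — the exchange format of the mapping pipeline.

#' Write a mesh or point cloud with scalar fields to legacy VTK
#'
#' @param path Output `.vtk` file.
#' @param points n x 3 matrix, mm (or a [tri_mesh()], whose vertices and
#'   triangles are used).
#' @param triangles Optional m x 3 triangle indices (1-based); ignored when
#'   `points` is a mesh.
#' @param point_data Named list of length-n numeric vectors.
#' @param cell_data Named list of length-m numeric vectors.
#' @return `path`, invisibly.
#' @export
write_vtk <- function(path, points, triangles = NULL, point_data = list(),
                      cell_data = list()) {
  if (inherits(points, "tri_mesh")) {
    triangles <- points$triangles
    points <- points$vertices
  }
  points <- as.matrix(points)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "atriafit export", "ASCII",
               "DATASET POLYDATA",
               sprintf("POINTS %d double", nrow(points))), con)
  writeLines(apply(points, 1, function(r) paste(format(r, digits = 10),
                                                collapse = " ")), con)
  if (!is.null(triangles)) {
    m <- nrow(triangles)
    writeLines(sprintf("POLYGONS %d %d", m, 4 * m), con)
    writeLines(apply(triangles - 1L, 1, function(r)
      paste(c(3L, r), collapse = " ")), con)
  }
  emit <- function(data, kind, n) {
    if (!length(data)) return()
    writeLines(sprintf("%s %d", kind, n), con)
    for (nm in names(data)) {
      writeLines(c(sprintf("SCALARS %s double 1", nm),
                   "LOOKUP_TABLE default"), con)
      v <- data[[nm]]
      v[!is.finite(v)] <- -1e30  # VTK has no NA; sentinel documented
      writeLines(format(v, digits = 10), con)
    }
  }
  emit(point_data, "POINT_DATA", nrow(points))
  emit(cell_data, "CELL_DATA", if (is.null(triangles)) 0L else nrow(triangles))
  invisible(path)
}

#' Read a legacy VTK polydata file written by [write_vtk()]
#'
#' Supports ASCII POLYDATA with POINTS, POLYGONS and scalar POINT_DATA /
#' CELL_DATA fields.
#'
#' @param path `.vtk` file.
#' @return List with `points`, `triangles` (or NULL), `point_data`,
#'   `cell_data` (named lists; the -1e30 sentinel is restored to `NA`).
#' @export
read_vtk <- function(path) {
  ln <- readLines(path)
  toks <- function(s) strsplit(trimws(s), "\\s+")[[1]]
  i <- grep("^POINTS", ln)[1]
  np <- as.integer(toks(ln[i])[2])
  pts <- matrix(as.numeric(unlist(strsplit(trimws(ln[(i + 1):(i + np)]),
                                           "\\s+"))), ncol = 3, byrow = TRUE)
  tri <- NULL
  ip <- grep("^POLYGONS", ln)
  if (length(ip)) {
    m <- as.integer(toks(ln[ip[1]])[2])
    rows <- strsplit(trimws(ln[(ip[1] + 1):(ip[1] + m)]), "\\s+")
    tri <- t(vapply(rows, function(r) as.integer(r[2:4]) + 1L, integer(3)))
  }
  read_fields <- function(start, n) {
    out <- list()
    j <- start
    while (j <= length(ln) && grepl("^SCALARS", ln[j])) {
      nm <- toks(ln[j])[2]
      vals <- as.numeric(ln[(j + 2):(j + 1 + n)])
      vals[vals <= -9.9e29] <- NA_real_
      out[[nm]] <- vals
      j <- j + 2 + n
    }
    out
  }
  pd <- list(); cd <- list()
  ipd <- grep("^POINT_DATA", ln)
  if (length(ipd)) pd <- read_fields(ipd[1] + 1, np)
  icd <- grep("^CELL_DATA", ln)
  if (length(icd) && !is.null(tri)) cd <- read_fields(icd[1] + 1, nrow(tri))
  list(points = pts, triangles = tri, point_data = pd, cell_data = cd)
}
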