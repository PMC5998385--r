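# Triangulated surface meshes: construction, element geometry, edge
# extraction. Coordinates are in mm throughout.

#' Triangulated surface mesh
#'
#' @param vertices n x 3 numeric matrix of vertex coordinates, mm.
#' @param triangles m x 3 integer matrix of vertex indices (1-based).
#' @return Object of class `tri_mesh`.
#' @export
tri_mesh <- function(vertices, triangles) {
  vertices <- as.matrix(vertices); storage.mode(vertices) <- "double"
  triangles <- as.matrix(triangles); storage.mode(triangles) <- "integer"
  if (ncol(vertices) != 3 || ncol(triangles) != 3)
    stop("vertices must be n x 3, triangles m x 3", call. = FALSE)
  if (any(triangles < 1L) || any(triangles > nrow(vertices)))
    stop("triangle indices out of range", call. = FALSE)
  if (any(!is.finite(vertices)))
    stop("vertex coordinates must be finite", call. = FALSE)
  structure(list(vertices = vertices, triangles = triangles),
            class = "tri_mesh")
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat(sprintf("triangle mesh: %d vertices, %d triangles, area %.1f mm^2\n",
              nrow(x$vertices), nrow(x$triangles), sum(mesh_areas(x))))
  invisible(x)
}

#' Regular flat rectangular sheet mesh
#'
#' A structured right-triangle mesh of a `size_cm[1]` x `size_cm[2]` sheet
#' in the z = 0 plane, with target edge length `edge_mm`.
#'
#' @param size_cm Length-1 or -2 numeric, sheet extent in cm.
#' @param edge_mm Target edge length, mm.
#' @return A [tri_mesh()].
#' @export
sheet_mesh <- function(size_cm = 8, edge_mm = 1) {
  size_mm <- rep(size_cm, length.out = 2) * 10
  nx <- max(2L, round(size_mm[1] / edge_mm) + 1L)
  ny <- max(2L, round(size_mm[2] / edge_mm) + 1L)
  xs <- seq(0, size_mm[1], length.out = nx)
  ys <- seq(0, size_mm[2], length.out = ny)
  verts <- cbind(rep(xs, times = ny), rep(ys, each = nx), 0)
  id <- function(i, j) (j - 1L) * nx + i
  tris <- vector("list", 2L * (nx - 1L) * (ny - 1L)); k <- 0L
  for (j in seq_len(ny - 1L)) for (i in seq_len(nx - 1L)) {
    tris[[k <- k + 1L]] <- c(id(i, j), id(i + 1L, j), id(i + 1L, j + 1L))
    tris[[k <- k + 1L]] <- c(id(i, j), id(i + 1L, j + 1L), id(i, j + 1L))
  }
  tri_mesh(verts, do.call(rbind, tris))
}

#' Triangle areas of a mesh (mm^2)
#' @param mesh A [tri_mesh()].
#' @return Numeric vector of element areas.
#' @export
mesh_areas <- function(mesh) {
  v <- mesh$vertices; t <- mesh$triangles
  e1 <- v[t[, 2], ] - v[t[, 1], ]
  e2 <- v[t[, 3], ] - v[t[, 1], ]
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  0.5 * sqrt(rowSums(cr^2))
}

#' Triangle centroids of a mesh (mm)
#' @param mesh A [tri_mesh()].
#' @return m x 3 matrix of element centroids.
#' @export
mesh_centroids <- function(mesh) {
  v <- mesh$vertices; t <- mesh$triangles
  (v[t[, 1], ] + v[t[, 2], ] + v[t[, 3], ]) / 3
}

# unique undirected edges; optionally augmented with the opposite-vertex
# pair of each interior edge (reduces graph metrication error)
mesh_edges <- function(mesh, virtual = FALSE) {
  t <- mesh$triangles
  e <- rbind(t[, c(1, 2)], t[, c(2, 3)], t[, c(1, 3)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  if (!virtual) return(unique(e))
  key <- paste(e[, 1], e[, 2])
  opp <- c(t[, 3], t[, 1], t[, 2])  # opposite vertex of each listed edge
  extra <- lapply(names(which(table(key) == 2)), function(k) {
    w <- which(key == k)
    sort(opp[w])
  })
  unique(rbind(unique(e), do.call(rbind, extra)))
}

# index of the nearest mesh vertex to each query point (rows of p, mm)
nearest_vertex <- function(mesh, p) {
  p <- matrix(p, ncol = 3)
  vapply(seq_len(nrow(p)), function(i) {
    which.min(colSums((t(mesh$vertices) - p[i, ])^2))
  }, integer(1))
}
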