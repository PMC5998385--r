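# Small 2D Delaunay triangulation (Bowyer-Watson). Point sets here are tiny
# (catheter snapshots, ~10 sites), so an O(n^2) incremental insertion with
# exact-enough double arithmetic is appropriate.

circumcircle2d <- function(a, b, c) {
  d <- 2 * (a[1] * (b[2] - c[2]) + b[1] * (c[2] - a[2]) + c[1] * (a[2] - b[2]))
  scale <- max(abs(c(a, b, c)), 1)
  if (abs(d) < 1e-12 * scale^2) return(NULL)  # (near-)collinear
  a2 <- sum(a^2); b2 <- sum(b^2); c2 <- sum(c^2)
  ux <- (a2 * (b[2] - c[2]) + b2 * (c[2] - a[2]) + c2 * (a[2] - b[2])) / d
  uy <- (a2 * (c[1] - b[1]) + b2 * (a[1] - c[1]) + c2 * (b[1] - a[1])) / d
  c(ux, uy, (a[1] - ux)^2 + (a[2] - uy)^2)
}

#' Delaunay triangulation of 2D points (Bowyer-Watson)
#'
#' Incremental insertion with a super-triangle; suitable for the small
#' point sets of a catheter snapshot. Cocircular ties resolve arbitrarily
#' (both diagonals are valid Delaunay triangulations).
#'
#' @param pts An n x 2 numeric matrix.
#' @return An m x 3 integer matrix of triangle vertex indices into `pts`.
#' @export
delaunay2d <- function(pts) {
  pts <- as.matrix(pts)
  n <- nrow(pts)
  if (n < 3) stop("need at least 3 points to triangulate", call. = FALSE)
  rng <- apply(pts, 2, range)
  span <- max(rng[2, ] - rng[1, ], 1e-9)
  ctr <- colMeans(rng)
  M <- 20 * span
  super <- rbind(ctr + M * c(cos(pi / 2), sin(pi / 2)),
                 ctr + M * c(cos(7 * pi / 6), sin(7 * pi / 6)),
                 ctr + M * c(cos(11 * pi / 6), sin(11 * pi / 6)))
  all_pts <- rbind(pts, super)
  tris <- matrix(n + 1:3, nrow = 1)
  cc <- matrix(circumcircle2d(super[1, ], super[2, ], super[3, ]), nrow = 1)

  for (ip in seq_len(n)) {
    p <- all_pts[ip, ]
    bad <- which((p[1] - cc[, 1])^2 + (p[2] - cc[, 2])^2 <= cc[, 3] * (1 + 1e-12))
    if (!length(bad)) stop("point outside all circumcircles; degenerate input",
                           call. = FALSE)
    # boundary of the cavity: edges of bad triangles appearing exactly once
    edges <- do.call(rbind, lapply(bad, function(t) {
      v <- tris[t, ]
      rbind(sort(v[1:2]), sort(v[2:3]), sort(v[c(1, 3)]))
    }))
    key <- paste(edges[, 1], edges[, 2])
    boundary <- edges[key %in% names(which(table(key) == 1)), , drop = FALSE]
    tris <- tris[-bad, , drop = FALSE]
    cc <- cc[-bad, , drop = FALSE]
    for (e in seq_len(nrow(boundary))) {
      v <- c(boundary[e, ], ip)
      circ <- circumcircle2d(all_pts[v[1], ], all_pts[v[2], ], all_pts[v[3], ])
      if (is.null(circ)) next  # skip slivers with the super-triangle frame
      tris <- rbind(tris, v)
      cc <- rbind(cc, circ)
    }
  }
  keep <- apply(tris, 1, function(v) all(v <= n))
  out <- tris[keep, , drop = FALSE]
  if (!nrow(out))
    stop("degenerate triangulation (points collinear?)", call. = FALSE)
  dimnames(out) <- NULL
  out
}
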