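# Extrapolation of per-electrode fits over the whole surface: Euclidean
# nearest-neighbour assignment per vertex (parameters) and per element
# centroid (diffusion), plus equal-width conductivity binning.

#' Surface model: mesh + heterogeneous electrophysiology fields
#'
#' @param mesh A [tri_mesh()].
#' @param vertex_params Data frame, one row per vertex: columns `tau_in`,
#'   `tau_out`, `tau_open`, `tau_close` (ms) and optionally the markers.
#' @param element_D Numeric vector, diffusion per element, cm^2/ms.
#' @param v_gate Gate threshold shared by all vertices.
#' @param provenance Optional data frame (source electrode, distance) per
#'   vertex.
#' @return Object of class `surface_model`.
#' @export
surface_model <- function(mesh, vertex_params, element_D, v_gate = 0.1,
                          provenance = NULL) {
  stopifnot(inherits(mesh, "tri_mesh"))
  if (nrow(vertex_params) != nrow(mesh$vertices))
    stop("vertex_params must have one row per vertex", call. = FALSE)
  if (length(element_D) != nrow(mesh$triangles))
    stop("element_D must have one value per triangle", call. = FALSE)
  need <- c("tau_in", "tau_out", "tau_open", "tau_close")
  miss <- setdiff(need, names(vertex_params))
  if (length(miss))
    stop("vertex_params missing: ", paste(miss, collapse = ", "), call. = FALSE)
  if (any(!is.finite(element_D)) || any(element_D <= 0))
    stop("element_D must be finite and > 0", call. = FALSE)
  structure(list(mesh = mesh, vertex_params = vertex_params,
                 element_D = element_D, v_gate = v_gate,
                 provenance = provenance),
            class = "surface_model")
}

#' @export
print.surface_model <- function(x, ...) {
  cat(sprintf("surface model: %d vertices, %d elements, D in [%.3g, %.3g] cm^2/ms\n",
              nrow(x$mesh$vertices), nrow(x$mesh$triangles),
              min(x$element_D), max(x$element_D)))
  invisible(x)
}

# nearest-electrode index for each row of `points`, ties to lowest electrode id
nn_assign <- function(points, electrode_pos) {
  d2 <- outer(rowSums(points^2), rowSums(electrode_pos^2), "+") -
    2 * points %*% t(electrode_pos)
  # which.min on each row returns the first (lowest id) minimiser
  apply(d2, 1, which.min)
}

#' Map per-electrode fits onto a mesh by nearest neighbour
#'
#' Every vertex takes the mMS parameters of its Euclidean-nearest fitted
#' electrode (ties to the lowest electrode id); every element takes the
#' diffusion coefficient of the electrode nearest its centroid. The map is
#' idempotent: applying it to its own output changes nothing.
#'
#' @param fits List of `fit_result` objects.
#' @param positions n_electrode x 3 matrix of electrode positions, mm.
#' @param mesh A [tri_mesh()].
#' @param v_gate Gate threshold.
#' @return A [surface_model()], with provenance (source electrode id and
#'   distance per vertex).
#' @export
nearest_neighbour_map <- function(fits, positions, mesh, v_gate = 0.1) {
  if (!length(fits)) stop("no fitted electrodes to map", call. = FALSE)
  positions <- as.matrix(positions)
  stopifnot(nrow(positions) == length(fits))
  tab <- fits_to_table(fits)
  vidx <- nn_assign(mesh$vertices, positions)
  eidx <- nn_assign(mesh_centroids(mesh), positions)
  vp <- tab[vidx, c("tau_in", "tau_out", "tau_open", "tau_close",
                    "cv_max", "apd_max", "h_min"), drop = FALSE]
  rownames(vp) <- NULL
  dist <- sqrt(rowSums((mesh$vertices - positions[vidx, , drop = FALSE])^2))
  surface_model(mesh, vp, element_D = tab$D[eidx], v_gate = v_gate,
                provenance = data.frame(electrode = tab$electrode[vidx],
                                        distance_mm = dist))
}

#' Bin per-element conductivities into a fixed number of element sets
#'
#' Equal-width bins over `[min(D), max(D)]`; each bin's representative
#' value is the mean of its members, so the per-element binning error is
#' bounded by the bin width `(max - min)/n_bins`.
#'
#' @param D Numeric vector of per-element diffusion values.
#' @param n_bins Number of bins (default 200).
#' @return List with `bin` (integer per element), `representative` (value
#'   per occupied bin, named by bin id), `D_binned` (per element).
#' @export
bin_conductivities <- function(D, n_bins = 200) {
  if (n_bins < 1) stop("n_bins must be >= 1", call. = FALSE)
  rng <- range(D)
  if (rng[1] == rng[2]) {
    return(list(bin = rep(1L, length(D)),
                representative = stats::setNames(rng[1], "1"),
                D_binned = rep(rng[1], length(D))))
  }
  width <- diff(rng) / n_bins
  bin <- pmin(n_bins, floor((D - rng[1]) / width) + 1L)
  rep_vals <- vapply(split(D, bin), mean, numeric(1))
  list(bin = as.integer(bin),
       representative = rep_vals,
       D_binned = as.numeric(rep_vals[as.character(bin)]))
}

#' Apply conductivity binning to a surface model
#'
#' @param model A [surface_model()].
#' @param n_bins Number of conductivity bins (default 200).
#' @return The model with `element_D` replaced by bin representatives and a
#'   `conductivity_bins` field added.
#' @export
bin_model_conductivities <- function(model, n_bins = 200) {
  b <- bin_conductivities(model$element_D, n_bins)
  model$element_D <- b$D_binned
  model$conductivity_bins <- b$bin
  model
}
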