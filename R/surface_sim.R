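# Heterogeneous isotropic monodomain on the triangulated surface: P1 FEM
# assembly, the clinical stimulus specification, S1S2 pacing and per-vertex
# LAT extraction (upward gate-threshold crossing of the premature beat).

#' Assemble P1 finite-element operators on a surface model
#'
#' Linear elements on triangles embedded in 3D; element-wise diffusion from
#' the model's (binned) conductivity field; lumped mass (one third of the
#' element area to each vertex); zero-flux boundary is natural. Stiffness
#' row sums vanish (constants are in the null space) and the mass entries
#' sum to the total surface area.
#'
#' @param model A [surface_model()].
#' @return List with `K` (sparse stiffness, mm^2/ms scale), `mass` (lumped
#'   mass vector, mm^2).
#' @export
assemble_fem <- function(model) {
  mesh <- model$mesh
  v <- mesh$vertices; tri <- mesh$triangles
  m <- nrow(tri)
  areas <- mesh_areas(mesh)
  bad <- which(areas < 1e-9)
  if (length(bad))
    stop("degenerate (zero-area) triangles: ",
         paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
  D_mm <- model$element_D * 100  # cm^2/ms -> mm^2/ms

  ii <- integer(9 * m); jj <- integer(9 * m); xx <- numeric(9 * m)
  pos <- 0L
  for (e in seq_len(m)) {
    id <- tri[e, ]
    p1 <- v[id[1], ]; p2 <- v[id[2], ]; p3 <- v[id[3], ]
    u <- p2 - p1; w <- p3 - p1
    lu <- sqrt(sum(u^2)); e1 <- u / lu
    w_perp <- w - sum(w * e1) * e1
    e2 <- w_perp / sqrt(sum(w_perp^2))
    q <- rbind(c(0, 0), c(lu, 0), c(sum(w * e1), sum(w * e2)))
    # gradients of the three hat functions: rows of the inverse mapping
    Mlocal <- cbind(1, q)
    G <- solve(Mlocal)[2:3, , drop = FALSE]      # 2 x 3: [dx; dy] per hat
    Ke <- areas[e] * D_mm[e] * crossprod(G)      # 3 x 3
    idx <- pos + 1:9
    ii[idx] <- rep(id, times = 3)
    jj[idx] <- rep(id, each = 3)
    xx[idx] <- as.vector(Ke)
    pos <- pos + 9L
  }
  K <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                            dims = rep(nrow(v), 2))
  mass <- numeric(nrow(v))
  for (k in 1:3) {
    contrib <- tapply(areas / 3, tri[, k], sum)
    iv <- as.integer(names(contrib))
    mass[iv] <- mass[iv] + as.numeric(contrib)
  }
  list(K = K, mass = mass)
}

#' Stimulus specification
#'
#' The clinical surrogate for remote pacing: a current of `amplitude`
#' (1/ms) and `duration_ms` applied on a disk of radius `radius_cm` around
#' `centre`; the disk radius (default 1 cm) encodes the uncertainty of the
#' effective entry site.
#'
#' @param centre Length-3 numeric, disk centre, mm.
#' @param radius_cm Disk radius, cm (default 1).
#' @param amplitude Applied current, 1/ms (default 4).
#' @param duration_ms Pulse duration, ms (default 0.6).
#' @return Object of class `stimulus_spec`.
#' @export
stimulus_spec <- function(centre, radius_cm = 1, amplitude = 4,
                          duration_ms = 0.6) {
  if (radius_cm <= 0 || duration_ms <= 0)
    stop("radius and duration must be > 0", call. = FALSE)
  structure(list(centre = as.numeric(centre), radius_cm = radius_cm,
                 amplitude = amplitude, duration_ms = duration_ms),
            class = "stimulus_spec")
}

#' Surface simulation configuration
#'
#' Presets: `"reference"` (dt_ode = 5 us, dt_pde = 50 us) and `"desk"`
#' (dt_ode = 20 us, dt_pde = 200 us).
#'
#' @param dt_ode_us,dt_pde_us Reaction / diffusion time steps,
#'   microseconds; PDE step must be an integer multiple of the ODE step.
#' @param t_end_ms Simulation end time; `NULL` chooses automatically from
#'   the mesh extent and the slowest leading-order CV in the model.
#' @param lat_threshold LAT detection threshold; `NULL` uses the model's
#'   `v_gate`.
#' @param preset `"desk"` or `"reference"`.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(dt_ode_us = NULL, dt_pde_us = NULL, t_end_ms = NULL,
                       lat_threshold = NULL, preset = c("desk", "reference")) {
  preset <- match.arg(preset)
  defaults <- switch(preset,
    reference = list(dt_ode_us = 5, dt_pde_us = 50),
    desk  = list(dt_ode_us = 20, dt_pde_us = 200))
  if (is.null(dt_ode_us)) dt_ode_us <- defaults$dt_ode_us
  if (is.null(dt_pde_us)) dt_pde_us <- defaults$dt_pde_us
  nsub <- dt_pde_us / dt_ode_us
  if (abs(nsub - round(nsub)) > 1e-9 || nsub < 1)
    stop("dt_pde must be an integer multiple of dt_ode", call. = FALSE)
  structure(list(dt_ode_us = dt_ode_us, dt_pde_us = dt_pde_us,
                 t_end_ms = t_end_ms, lat_threshold = lat_threshold,
                 preset = preset),
            class = "sim_config")
}

# crude transit-time bound used for automatic end times
slowest_transit_ms <- function(model) {
  vp <- model$vertex_params
  cv_cm_ms <- (1 - 2 * model$v_gate) *
    sqrt(min(model$element_D) / (2 * max(vp$tau_in)))
  ext <- apply(model$mesh$vertices, 2, function(z) diff(range(z)))
  diam_mm <- sqrt(sum(ext^2))
  diam_mm / (max(cv_cm_ms, 0.005) * 10)
}

#' Simulate S1S2 pacing on a surface model
#'
#' Applies the full drive train plus the premature beat inside the stimulus
#' disk and integrates the heterogeneous monodomain model. The LAT of a
#' vertex is the first upward crossing of the gate threshold during the
#' premature-beat window; vertices that never cross are blocked
#' (functional block).
#'
#' @param model A [surface_model()].
#' @param stim A [stimulus_spec()].
#' @param protocol A [pacing_protocol()].
#' @param s2 Premature coupling interval, ms; `NULL` runs the drive train
#'   only (LAT window then starts at the last drive beat).
#' @param cfg A [sim_config()].
#' @param record_positions Optional k x 3 matrix (mm); transmembrane
#'   potential at the nearest vertices is recorded every PDE step.
#' @param stim_vertices Optional explicit stimulus vertex set overriding
#'   the disk (e.g. an edge strip for plane-wave studies).
#' @return Object of class `lat_map`: `lat` (absolute ms per vertex, `NA`
#'   = blocked), `onset` (premature stimulus time), `time`, `traces`,
#'   `record_vertex`, plus the stimulus vertex set.
#' @export
simulate_pacing <- function(model, stim, protocol = pacing_protocol(),
                            s2 = protocol$s2_start, cfg = sim_config(),
                            record_positions = NULL, stim_vertices = NULL) {
  mesh <- model$mesh
  ops <- assemble_fem(model)
  if (is.null(stim_vertices)) {
    d2 <- colSums((t(mesh$vertices) - stim$centre)^2)
    stim_idx <- which(d2 <= (stim$radius_cm * 10)^2)
  } else stim_idx <- stim_vertices
  if (!length(stim_idx))
    stop("stimulus disk does not intersect the mesh", call. = FALSE)

  drive <- protocol$s1 * (seq_len(protocol$n_s1) - 1)
  if (is.null(s2)) {
    stim_times <- drive
    onset <- drive[length(drive)]
  } else {
    onset <- drive[length(drive)] + s2
    stim_times <- c(drive, onset)
  }
  t_end <- cfg$t_end_ms %||% (onset + 1.5 * slowest_transit_ms(model) + 250)
  rec_idx <- if (is.null(record_positions)) integer(0) else
    nearest_vertex(mesh, as.matrix(record_positions))

  Kc <- methods::as(ops$K, "CsparseMatrix")  # symmetric: CSC slots double as CSR
  vp <- model$vertex_params
  res <- surface_run_cpp(
    Kp = Kc@p, Kj = Kc@i, Kx = Kc@x, mass = ops$mass,
    tau_in = vp$tau_in, tau_out = vp$tau_out,
    tau_open = vp$tau_open, tau_close = vp$tau_close,
    vgate = model$v_gate,
    stim_idx0 = as.integer(stim_idx - 1L),
    stim_amp = stim$amplitude, stim_dur = stim$duration_ms,
    stim_times = stim_times,
    t_end = t_end, dt_ode = cfg$dt_ode_us * 1e-3,
    dt_pde = cfg$dt_pde_us * 1e-3,
    lat_window_start = onset,
    lat_thresh = cfg$lat_threshold %||% model$v_gate,
    record_idx0 = as.integer(rec_idx - 1L))
  structure(list(lat = res$lat, onset = onset, time = res$time,
                 traces = res$traces, record_vertex = rec_idx,
                 stim_vertices = stim_idx, s2 = s2,
                 stim_times = stim_times),
            class = "lat_map")
}

#' @export
print.lat_map <- function(x, ...) {
  nb <- sum(is.na(x$lat))
  cat(sprintf("LAT map: %d vertices, %d blocked; onset %g ms; LAT span [%.1f, %.1f] ms\n",
              length(x$lat), nb, x$onset,
              suppressWarnings(min(x$lat, na.rm = TRUE)),
              suppressWarnings(max(x$lat, na.rm = TRUE))))
  invisible(x)
}

#' Sample a LAT map at electrode positions
#'
#' Value at the mesh vertex nearest each position; blocked vertices yield
#' `NA`.
#'
#' @param lat_map A `lat_map` from [simulate_pacing()] (or any per-vertex
#'   numeric vector).
#' @param positions k x 3 matrix, mm.
#' @param mesh The [tri_mesh()] the map lives on.
#' @return Numeric vector of length k.
#' @export
sample_at_electrodes <- function(lat_map, positions, mesh) {
  lat <- if (inherits(lat_map, "lat_map")) lat_map$lat else lat_map
  lat[nearest_vertex(mesh, as.matrix(positions))]
}
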