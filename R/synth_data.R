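# Synthetic ground-truth cases: heterogeneous sheet models with known
# parameters, virtual five-spline (PentaRay-style) catheter recordings of
# the S1S2 protocol, and the full end-to-end pipeline (record -> process ->
# fit -> map -> simulate -> validate) without clinical data.

#' Ground-truth sheet case with Voronoi-patch heterogeneity
#'
#' A flat rectangular sheet whose vertices are partitioned into `n_regions`
#' Voronoi patches around random seed points; each patch draws its
#' `cv_max` and `apd_max` from in-grid value pools (defaults 60-120 cm/s by
#' 10 and 150-240 ms by 15, the physiological mid-range of the database
#' axes), with `tau_in`, `h_min` and `tau_open` held at mid-grid values.
#' Two pacing sites emulate remote entry: site A (fitting, CS-like) at the
#' mid-left boundary and site B (held-out, HRA-like) at the mid-top. Fully
#' deterministic for a fixed seed.
#'
#' @param size_cm Sheet extent, cm (default 8).
#' @param n_regions Number of Voronoi parameter patches (default 4).
#' @param edge_mm Mesh edge length, mm (default 1).
#' @param protocol A [pacing_protocol()].
#' @param seed Integer random seed.
#' @param cv_pool,apd_pool Marker value pools sampled per region.
#' @param tau_in,h_min,tau_open Fixed markers shared by all regions.
#' @param lat_jitter_sd_ms LAT measurement jitter SD, ms (default 0).
#' @param dropout_prob Per-recording dropout probability (default 0).
#' @param snapshot_centres Optional k x 2 matrix of catheter hub centres
#'   (mm, in-sheet coordinates); default two placements straddling the
#'   sheet centre.
#' @return Object of class `ground_truth_case`.
#' @export
make_sheet_case <- function(size_cm = 8, n_regions = 4, edge_mm = 1,
                            protocol = pacing_protocol(), seed = 1,
                            cv_pool = seq(60, 120, by = 10),
                            apd_pool = seq(150, 240, by = 15),
                            tau_in = 0.28, h_min = 0.3, tau_open = 105,
                            lat_jitter_sd_ms = 0, dropout_prob = 0,
                            snapshot_centres = NULL) {
  mesh <- sheet_mesh(size_cm, edge_mm)
  size_mm <- rep(size_cm, length.out = 2) * 10
  set.seed(seed)
  centres <- cbind(stats::runif(n_regions, 0.1, 0.9) * size_mm[1],
                   stats::runif(n_regions, 0.1, 0.9) * size_mm[2], 0)
  region <- nn_assign(mesh$vertices, centres)
  draw <- function(pool, n) pool[sample.int(length(pool), n, replace = TRUE)]
  region_markers <- data.frame(
    cv_max = draw(cv_pool, n_regions),
    apd_max = draw(apd_pool, n_regions),
    h_min = h_min, tau_in = tau_in, tau_open = tau_open)

  inv <- lapply(seq_len(n_regions), function(r) {
    invert_markers(cell_markers(cv_max = region_markers$cv_max[r],
                                apd_max = region_markers$apd_max[r],
                                h_min = h_min, tau_in = tau_in,
                                tau_open = tau_open))
  })
  par_tab <- do.call(rbind, lapply(inv, function(z)
    data.frame(tau_in = z$params$tau_in, tau_out = z$params$tau_out,
               tau_open = z$params$tau_open, tau_close = z$params$tau_close,
               D = z$D)))
  vp <- par_tab[region, c("tau_in", "tau_out", "tau_open", "tau_close")]
  rownames(vp) <- NULL
  vp$cv_max <- region_markers$cv_max[region]
  vp$apd_max <- region_markers$apd_max[region]
  vp$h_min <- h_min
  elem_region <- region[nearest_vertex(mesh, mesh_centroids(mesh))]
  model <- surface_model(mesh, vp, element_D = par_tab$D[elem_region])

  # five catheter placements (50 bipoles) spread over the sheet, echoing
  # the clinical recommendation of >= 50 mapping points with broad
  # coverage. All sit >= 4 cm from the fitting pacing site so the premature
  # front is locally planar there (negligible curvature bias in the
  # LAT-gradient CV estimator) while spanning a wide angle for the onset
  # search.
  if (is.null(snapshot_centres))
    snapshot_centres <- rbind(c(0.45, 0.20), c(0.45, 0.80), c(0.55, 0.50),
                              c(0.80, 0.30), c(0.80, 0.70)) %*% diag(size_mm)
  pacing <- list(A = c(0, size_mm[2] / 2, 0),
                 B = c(size_mm[1] / 2, size_mm[2], 0))
  structure(list(model = model, region = region,
                 region_markers = region_markers,
                 protocol = protocol, seed = seed,
                 pacing_sites = pacing,
                 snapshot_centres = snapshot_centres,
                 noise = list(lat_jitter_sd_ms = lat_jitter_sd_ms,
                              dropout_prob = dropout_prob),
                 size_mm = size_mm),
            class = "ground_truth_case")
}

#' @export
print.ground_truth_case <- function(x, ...) {
  cat(sprintf("ground-truth case: %g x %g mm sheet, %d regions, seed %d\n",
              x$size_mm[1], x$size_mm[2], nrow(x$region_markers), x$seed))
  print(x$region_markers)
  invisible(x)
}

#' Virtual five-spline catheter geometry
#'
#' Five splines at 72 degrees around a 2 mm hub; four 1 mm electrodes per
#' spline, centres 4 mm apart starting 1 mm beyond the hub edge (radii 3,
#' 7, 11, 15 mm). Each spline contributes a proximal and a distal bipole
#' (electrode pairs 1-2 and 3-4), so one placement yields 10 bipoles.
#'
#' @param centre Length-2 or -3 hub centre, mm (z = 0 assumed if absent).
#' @param orientation_deg Rotation of the first spline, degrees.
#' @param mesh A [tri_mesh()] the footprint must lie on.
#' @return Object of class `pentaray_snapshot`: `poles` (20 x 3), `spline`,
#'   `bipole_pos` (10 x 3 midpoints), `pole_a`, `pole_b` (index into
#'   `poles` per bipole).
#' @export
place_pentaray <- function(centre, orientation_deg = 0, mesh) {
  centre <- c(as.numeric(centre), 0)[1:3]
  radii <- c(3, 7, 11, 15)
  ang <- (orientation_deg + 72 * (0:4)) * pi / 180
  poles <- do.call(rbind, lapply(seq_along(ang), function(s) {
    dir <- c(cos(ang[s]), sin(ang[s]), 0)
    t(vapply(radii, function(r) centre + r * dir, numeric(3)))
  }))
  # footprint must stay on the mesh: each pole within one edge of a vertex
  edge <- stats::median(sqrt(rowSums((mesh$vertices[mesh$triangles[, 1], ] -
                                      mesh$vertices[mesh$triangles[, 2], ])^2)))
  nv <- nearest_vertex(mesh, poles)
  d <- sqrt(rowSums((poles - mesh$vertices[nv, , drop = FALSE])^2))
  if (any(d > 2 * edge))
    stop("catheter footprint leaves the mesh", call. = FALSE)
  spline <- rep(1:5, each = 4)
  pole_a <- as.integer(outer(c(1, 3), 4 * (0:4), "+"))   # 1,3, 5,7, ...
  pole_b <- pole_a + 1L
  bipole_pos <- (poles[pole_a, , drop = FALSE] +
                 poles[pole_b, , drop = FALSE]) / 2
  structure(list(poles = poles, spline = spline, bipole_pos = bipole_pos,
                 pole_a = pole_a, pole_b = pole_b, centre = centre),
            class = "pentaray_snapshot")
}

#' Record virtual catheter electrograms for one pacing site
#'
#' For each premature interval, runs the ground-truth monodomain
#' simulation, synthesises bipolar electrograms at every catheter pole
#' pair as `(vm_b - vm_a)/2` (the 1D extracellular identity, used as the
#' surface surrogate), detects LATs as the first supra-threshold
#' electrogram extremum of the premature beat, and applies the case's LAT
#' jitter and dropout noise. Capture requires a detected deflection.
#'
#' @param case A [make_sheet_case()] result.
#' @param site `"A"` (fitting site) or `"B"` (held-out site).
#' @param s2_values s2 subset to record (default: full protocol ladder).
#' @param cfg A [sim_config()].
#' @param stim A [stimulus_spec()] overriding the site default.
#' @return Object of class `case_recordings`: `snapshots` (list of
#'   `pentaray_snapshot`), `positions` (bipoles x 3), `lat` (bipoles x s2,
#'   absolute ms), `captured`, `s2`, `site`, and the raw `traces` per s2.
#' @export
record_case <- function(case, site = "A", s2_values = NULL,
                        cfg = sim_config(), stim = NULL) {
  if (is.null(s2_values)) s2_values <- s2_ladder(case$protocol)
  snaps <- lapply(seq_len(nrow(case$snapshot_centres)), function(k)
    place_pentaray(case$snapshot_centres[k, ],
                   orientation_deg = 36 * (k - 1), mesh = case$model$mesh))
  poles <- do.call(rbind, lapply(snaps, `[[`, "poles"))
  n_per <- vapply(snaps, function(s) nrow(s$bipole_pos), integer(1))
  positions <- do.call(rbind, lapply(snaps, `[[`, "bipole_pos"))
  pole_a <- unlist(lapply(seq_along(snaps), function(k)
    snaps[[k]]$pole_a + 20 * (k - 1)))
  pole_b <- pole_a + 1L
  nb <- nrow(positions)

  if (is.null(stim))
    stim <- stimulus_spec(centre = case$pacing_sites[[site]])
  lat <- matrix(NA_real_, nb, length(s2_values))
  captured <- matrix(FALSE, nb, length(s2_values))
  traces <- vector("list", length(s2_values))
  set.seed(case$seed * 1000L + match(site, c("A", "B")))
  for (j in seq_along(s2_values)) {
    run <- simulate_pacing(case$model, stim, case$protocol,
                           s2 = s2_values[j], cfg = cfg,
                           record_positions = poles)
    bip <- (run$traces[, pole_b] - run$traces[, pole_a]) / 2
    traces[[j]] <- list(time = run$time, bipolar = bip)
    lat[, j] <- annotate_egm_beat(run$time, bip, run$onset)
    captured[, j] <- is.finite(lat[, j])
    jit <- stats::rnorm(nb, 0, case$noise$lat_jitter_sd_ms)
    lat[, j] <- lat[, j] + ifelse(captured[, j], jit, 0)
    drop <- stats::runif(nb) < case$noise$dropout_prob
    lat[drop, j] <- NA_real_
    captured[drop, j] <- FALSE
  }
  structure(list(snapshots = snaps, positions = positions,
                 snapshot_of = rep(seq_along(snaps), n_per),
                 lat = lat, captured = captured, s2 = s2_values,
                 site = site, stim = stim,
                 poles = poles, pole_a = pole_a, pole_b = pole_b),
            class = "case_recordings")
}

# Annotate the premature-beat LAT on each synthetic bipolar electrogram:
# conditioned (high-pass) trace, first extremum above 5% of the drive-train
# amplitude whose polarity matches the drive beat's (morphology matching —
# the premature wave shares the drive wave's direction, so the preceding
# beat's opposite-signed repolarisation deflection is rejected).
annotate_egm_beat <- function(time, bipolar, onset) {
  nb <- ncol(bipolar)
  out <- rep(NA_real_, nb)
  for (i in seq_len(nb)) {
    tr <- condition_egm(data.frame(time_ms = time, value = bipolar[, i]))
    pre <- which(tr$time_ms < onset)
    iref <- pre[which.max(abs(tr$value[pre]))]
    ref <- abs(tr$value[iref])
    if (ref < 1e-9) next
    out[i] <- detect_lat(tr, window = c(onset + 2, max(tr$time_ms)),
                         threshold = 0.05 * ref,
                         polarity = if (tr$value[iref] > 0) "positive"
                                    else "negative")
  }
  out
}

#' Process recordings into per-electrode fitting inputs
#'
#' Runs the electrogram-processing chain per catheter snapshot (CV field,
#' physiological cut-off, ERP), returning the measurement list that
#' [fit_all()] consumes plus the pooled electrode positions.
#'
#' @param rec A `case_recordings` object.
#' @param cutoff Physiological CV cut-off, cm/s.
#' @return List with `measurements` (list of `cv_measurement`) and
#'   `positions`.
#' @export
process_recordings <- function(rec, cutoff = 200) {
  meas <- list()
  for (k in unique(rec$snapshot_of)) {
    sel <- which(rec$snapshot_of == k)
    m <- snapshot_measurements(rec$positions[sel, , drop = FALSE],
                               rec$lat[sel, , drop = FALSE], rec$s2,
                               cutoff = cutoff)
    for (i in seq_along(m)) m[[i]]$electrode <- sel[i]
    meas <- c(meas, m)
  }
  list(measurements = meas, positions = rec$positions)
}

#' Run the complete personalisation pipeline on a synthetic case
#'
#' Site-A recordings are processed and fitted against the database, the
#' fitted parameters are mapped over the mesh (with conductivity binning),
#' the effective stimulus of each site is localised by the eikonal search
#' on the measured LATs at the longest coupling interval, the fitted model
#' is simulated at every validation s2 for both sites, and measured vs
#' simulated LATs are scored — site A tests reproduction, the held-out
#' site B tests prediction.
#'
#' @param case A [make_sheet_case()] result.
#' @param db A `restitution_db` to fit against.
#' @param s2_fit s2 values recorded for fitting (default: a 6-value subset
#'   of the ladder spanning plateau to short coupling).
#' @param s2_valid s2 values used for validation (default: `s2_fit`).
#' @param fit_cfg A [fit_config()].
#' @param cfg A [sim_config()].
#' @param onset `"eikonal"` (localise from measured LATs, the clinical
#'   procedure) or `"true"` (use the generating site; diagnostic only).
#' @param curvature_correction Correct measured CVs for wavefront
#'   curvature before the final fit (default TRUE). The premature front
#'   from a remote entry site is convex, so the LAT-gradient estimator
#'   reads `c_plane - D/r` at distance `r`; after a provisional fit
#'   supplies `D` per electrode and the onset search supplies `r`, the
#'   eikonal curvature relation restores the plane-wave speed that the
#'   1D restitution database tabulates.
#' @param n_bins Conductivity bins for the mapped model.
#' @return List: `reports` (site A and B `validation_report`s), `fits`,
#'   `model`, `onsets` (per-site `onset_search` or true centres),
#'   `recordings`.
#' @export
end_to_end_case <- function(case, db, s2_fit = NULL, s2_valid = NULL,
                            fit_cfg = fit_config(), cfg = sim_config(),
                            onset = c("eikonal", "true"),
                            curvature_correction = TRUE, n_bins = 200) {
  onset <- match.arg(onset)
  ladder <- s2_ladder(case$protocol)
  if (is.null(s2_fit))
    s2_fit <- ladder[unique(round(seq(1, length(ladder), length.out = 6)))]
  if (is.null(s2_valid)) s2_valid <- s2_fit

  rec_fit <- record_case(case, "A", s2_values = s2_fit, cfg = cfg)
  proc <- process_recordings(rec_fit)
  fits <- fit_all(proc$measurements, db, fit_cfg)
  if (curvature_correction) {
    # locate the fitting-site onset from the longest-coupling LATs, then
    # undo the convex-front curvature slowing D/r of each measured CV and
    # refit; D comes from the provisional fit
    j_max <- which.max(rec_fit$s2)
    cv_longest <- vapply(proc$measurements, function(m)
      m$cv[which.max(m$s2)], numeric(1))
    spd <- speed_field(case$model$mesh, proc$positions, cv_longest)
    os0 <- locate_onset(case$model$mesh, spd, proc$positions,
                        rec_fit$lat[, j_max])
    src <- case$model$mesh$vertices[os0$vertex, ]
    r_mm <- sqrt(rowSums(sweep(proc$positions, 2, src)^2))
    for (i in seq_along(proc$measurements)) {
      corr <- 1e4 * fits[[i]]$D / max(r_mm[i], 10)  # cm/s
      proc$measurements[[i]]$cv <- proc$measurements[[i]]$cv + corr
    }
    fits <- fit_all(proc$measurements, db, fit_cfg)
  }
  model <- nearest_neighbour_map(fits, proc$positions, case$model$mesh,
                                 v_gate = case$model$v_gate)
  model <- bin_model_conductivities(model, n_bins)

  recs <- list(A = rec_fit,
               B = record_case(case, "B", s2_values = s2_valid, cfg = cfg))
  if (!identical(s2_valid, s2_fit))
    recs$A <- record_case(case, "A", s2_values = s2_valid, cfg = cfg)

  reports <- list(); onsets <- list()
  for (site in c("A", "B")) {
    rec <- recs[[site]]
    j_max <- which.max(rec$s2)
    cv_longest <- vapply(proc$measurements, function(m)
      m$cv[which.max(m$s2)], numeric(1))
    spd <- speed_field(case$model$mesh, proc$positions, cv_longest)
    if (onset == "eikonal") {
      os <- locate_onset(case$model$mesh, spd, rec$positions,
                         rec$lat[, j_max])
      centre <- case$model$mesh$vertices[os$vertex, ]
      onsets[[site]] <- os
    } else {
      centre <- case$pacing_sites[[site]]
      onsets[[site]] <- centre
    }
    stim <- stimulus_spec(centre = centre)
    computed <- matrix(NA_real_, nrow(rec$positions), length(rec$s2))
    for (j in seq_along(rec$s2)) {
      run <- simulate_pacing(model, stim, case$protocol, s2 = rec$s2[j],
                             cfg = cfg, record_positions = rec$poles)
      # simulated LATs are annotated through the same virtual-electrogram
      # chain as the measurements, so the annotation convention cancels in
      # the comparison
      bip <- (run$traces[, rec$pole_b] - run$traces[, rec$pole_a]) / 2
      computed[, j] <- annotate_egm_beat(run$time, bip, run$onset)
    }
    # both matrices hold absolute times; the report's single global offset
    # absorbs the systematic shift between true and localised onsets
    reports[[site]] <- validation_report(rec$lat, computed, s2 = rec$s2)
  }
  list(reports = reports, fits = fits, model = model, onsets = onsets,
       recordings = recs)
}
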