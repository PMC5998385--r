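# 1D monodomain cable: configuration, S1S2 pacing protocol, simulation
# driver, extracellular potential, bipolar electrograms and CV restitution.
# The time-stepping core lives in src/cable.cpp.

#' 1D cable configuration
#'
#' Geometry, discretisation and electrode-assembly layout for the 1D
#' monodomain cable used to pre-compute restitution curves. Two presets are
#' provided: `"reference"` (dx = 200 um, dt_ode = 10 us, dt_pde = 100 us) at
#' full fidelity, and `"desk"` (dx = 500 um, dt_ode = 20 us,
#' dt_pde = 200 us) for interactive use and tests.
#'
#' The four recording poles form two bipolar pairs with `pole_spacing_mm`
#' within a pair and `pair_separation_mm` between pair barycentres, centred
#' in the domain to minimise boundary effects. The stimulus is applied at
#' the x = 0 end over `stim_length_mm` with a 2 ms pulse — the clinical
#' stimulator's pulse width, delivered at twice threshold so that capture
#' is limited by tissue refractoriness rather than by the source.
#'
#' @param length_cm Domain length, cm.
#' @param dx_um Mesh size, micrometres.
#' @param dt_ode_us Reaction (forward-Euler) step, microseconds.
#' @param dt_pde_us Diffusion (Crank-Nicolson) step, microseconds; must be
#'   an integer multiple of `dt_ode_us`.
#' @param stim_length_mm Stimulated region length at the cable end, mm.
#' @param stim_amplitude Applied current density, 1/ms.
#' @param stim_duration_ms Stimulus pulse width, ms.
#' @param pole_spacing_mm Distance between the two poles of a bipole, mm.
#' @param pair_separation_mm Distance between the barycentres of the two
#'   bipolar pairs, mm.
#' @param preset `"reference"` or `"desk"`; explicit arguments override preset
#'   values.
#' @return An object of class `cable_config`.
#' @export
cable_config <- function(length_cm = 10, dx_um = NULL, dt_ode_us = NULL,
                         dt_pde_us = NULL, stim_length_mm = 0.5,
                         stim_amplitude = 4, stim_duration_ms = 2,
                         pole_spacing_mm = 2, pair_separation_mm = 7,
                         preset = c("reference", "desk")) {
  preset <- match.arg(preset)
  defaults <- switch(preset,
    reference = list(dx_um = 200, dt_ode_us = 10, dt_pde_us = 100),
    desk  = list(dx_um = 500, dt_ode_us = 20, dt_pde_us = 200))
  if (is.null(dx_um)) dx_um <- defaults$dx_um
  if (is.null(dt_ode_us)) dt_ode_us <- defaults$dt_ode_us
  if (is.null(dt_pde_us)) dt_pde_us <- defaults$dt_pde_us
  if (dt_ode_us > dt_pde_us)
    stop("dt_ode must not exceed dt_pde", call. = FALSE)
  nsub <- dt_pde_us / dt_ode_us
  if (abs(nsub - round(nsub)) > 1e-9)
    stop("dt_pde must be an integer multiple of dt_ode", call. = FALSE)
  # electrode assembly must fit inside the domain
  half_span_cm <- (pair_separation_mm / 2 + pole_spacing_mm / 2) / 10
  if (half_span_cm >= length_cm / 2)
    stop("electrode assembly does not fit inside the cable", call. = FALSE)
  structure(list(length_cm = length_cm, dx_um = dx_um,
                 dt_ode_us = dt_ode_us, dt_pde_us = dt_pde_us,
                 stim_length_mm = stim_length_mm,
                 stim_amplitude = stim_amplitude,
                 stim_duration_ms = stim_duration_ms,
                 pole_spacing_mm = pole_spacing_mm,
                 pair_separation_mm = pair_separation_mm,
                 preset = preset),
            class = "cable_config")
}

#' S1S2 pacing protocol
#'
#' A drive train of `n_s1` beats at coupling interval `s1` followed by a
#' single premature stimulus at interval `s2`; sweeping `s2` down a
#' geometric ladder traces the restitution curve.
#'
#' @param s1 Drive-train interval, ms (default 470).
#' @param n_s1 Number of drive beats (default 2).
#' @param s2_start First (longest) premature interval, ms (default 343).
#' @param s2_decrement_fraction Fractional decrement per ladder step
#'   (default 0.02, i.e. 2% steps).
#' @param s2_floor Smallest tested interval, ms (default 200); the ladder
#'   stops at the last value >= the floor.
#' @return An object of class `pacing_protocol`.
#' @export
pacing_protocol <- function(s1 = 470, n_s1 = 2, s2_start = 343,
                            s2_decrement_fraction = 0.02, s2_floor = 200) {
  if (s1 <= 0 || s2_start <= 0 || s2_floor <= 0)
    stop("all intervals must be > 0", call. = FALSE)
  if (s2_decrement_fraction <= 0 || s2_decrement_fraction >= 1)
    stop("s2_decrement_fraction must be in (0, 1)", call. = FALSE)
  if (n_s1 < 1) stop("need at least one drive beat", call. = FALSE)
  if (s2_floor > s2_start)
    stop("s2_floor must not exceed s2_start", call. = FALSE)
  structure(list(s1 = s1, n_s1 = n_s1, s2_start = s2_start,
                 s2_decrement_fraction = s2_decrement_fraction,
                 s2_floor = s2_floor),
            class = "pacing_protocol")
}

#' The descending ladder of premature coupling intervals
#'
#' `s2_k = s2_start * (1 - f)^k`, truncated at the first value below
#' `s2_floor`. With the defaults (343 ms start, 2% steps, 200 ms floor) the
#' ladder has 27 values.
#'
#' @param protocol A [pacing_protocol()] object.
#' @return Numeric vector of s2 values, ms, strictly decreasing.
#' @export
s2_ladder <- function(protocol) {
  f <- 1 - protocol$s2_decrement_fraction
  k <- 0:ceiling(log(protocol$s2_floor / protocol$s2_start) / log(f) + 1)
  vals <- protocol$s2_start * f^k
  vals[vals >= protocol$s2_floor - 1e-9]
}

# pole node indices (0-based for C++) and x positions for the 2x2 assembly
cable_pole_nodes <- function(cfg) {
  dx_cm <- cfg$dx_um * 1e-4
  centre <- cfg$length_cm / 2
  half_pair <- cfg$pair_separation_mm / 20   # mm -> cm, half
  half_pole <- cfg$pole_spacing_mm / 20
  x <- centre + c(-half_pair - half_pole, -half_pair + half_pole,
                  half_pair - half_pole, half_pair + half_pole)
  idx <- round(x / dx_cm)
  n_nodes <- round(cfg$length_cm / dx_cm) + 1
  stopifnot(all(idx >= 0 & idx < n_nodes))
  list(idx0 = as.integer(idx), x_cm = idx * dx_cm, n_nodes = as.integer(n_nodes))
}

# post-stimulus observation window: transit of the slowest relevant wave to
# the far pole plus repolarisation margin
cable_post_window <- function(p, D, cfg) {
  cv_cm_ms <- (1 - 2 * p$v_gate) * sqrt(D / (2 * p$tau_in))  # leading order
  travel <- (cfg$length_cm / 2 + 0.5) / max(cv_cm_ms, 0.005)
  min(300 + 1.6 * travel, 2500)
}

#' Run the 1D monodomain cable for one premature interval
#'
#' Simulates the full drive train plus one s2 beat and returns the
#' transmembrane potential sampled at the four recording poles (plus its
#' spatial mean, needed for the extracellular closed form) at `dt_pde`
#' resolution. With `s2 = NULL` only the drive train is run.
#'
#' @param p An [mms_params()] object.
#' @param D Diffusion coefficient, cm^2/ms.
#' @param cfg A [cable_config()] object.
#' @param protocol A [pacing_protocol()] object.
#' @param s2 Premature coupling interval, ms, or `NULL`.
#' @return A list with `time` (ms), `vm` (time x 4 matrix at poles
#'   a1,b1,a2,b2 ordered away from the stimulus), `vm_mean`, `pole_x_cm`,
#'   `drive_times`, `s2_time` (NA if no premature beat).
#' @export
run_cable <- function(p, D, cfg = cable_config(), protocol = pacing_protocol(),
                      s2 = protocol$s2_start) {
  poles <- cable_pole_nodes(cfg)
  drive <- protocol$s1 * (seq_len(protocol$n_s1) - 1)
  branch <- if (is.null(s2)) numeric(0) else drive[length(drive)] + s2
  post <- cable_post_window(p, D, cfg)
  res <- cable_ladder_cpp(
    tau = c(p$tau_in, p$tau_out, p$tau_open, p$tau_close),
    vgate = p$v_gate, D = D,
    n_nodes = poles$n_nodes, dx_cm = cfg$dx_um * 1e-4,
    dt_ode_ms = cfg$dt_ode_us * 1e-3, dt_pde_ms = cfg$dt_pde_us * 1e-3,
    stim_len_cm = cfg$stim_length_mm / 10,
    stim_amp = cfg$stim_amplitude, stim_dur_ms = cfg$stim_duration_ms,
    drive_times = drive, branch_times = branch,
    post_ms = post, sample_idx0 = poles$idx0)
  if (length(branch)) {
    trunk <- res$trunk; br <- res$branches[[1]]
    out <- list(time = c(trunk$time, br$time),
                vm = rbind(trunk$vm, br$vm),
                vm_mean = c(trunk$vm_mean, br$vm_mean),
                s2_time = branch)
  } else {
    out <- list(time = res$trunk$time, vm = res$trunk$vm,
                vm_mean = res$trunk$vm_mean, s2_time = NA_real_)
  }
  out$pole_x_cm <- poles$x_cm
  out$drive_times <- drive
  out
}

#' Extracellular potential of a 1D monodomain snapshot
#'
#' Closed-form solution of `d^2/dx^2 (vm + 2 phi_e) = 0` with zero-flux ends
#' and the zero-mean convention: `phi_e = (mean(vm) - vm) / 2`. Accepts a
#' vector (one snapshot) or a matrix (rows = time, columns = space).
#'
#' @param vm Transmembrane potential over the grid.
#' @return `phi_e`, same shape as `vm`; each snapshot has zero mean.
#' @export
extracellular <- function(vm) {
  if (is.matrix(vm)) return((rowMeans(vm) - vm) / 2)
  (mean(vm) - vm) / 2
}

#' Bipolar electrogram from an extracellular-potential history
#'
#' The bipolar signal is the difference of the extracellular potential at
#' the two poles of the electrode, `b(t) = phi_e(a, t) - phi_e(b, t)`; with
#' the monodomain closed form this equals `(vm(b,t) - vm(a,t)) / 2`.
#'
#' @param phi Matrix of extracellular potential (rows = time, columns =
#'   recording sites), or of `vm` with `from_vm = TRUE`.
#' @param pole_a,pole_b Column indices of the two poles.
#' @param from_vm If `TRUE`, `phi` holds transmembrane potential and the
#'   identity `(vm_b - vm_a)/2` is applied directly.
#' @return Numeric vector, the bipolar trace over time.
#' @export
bipolar_signal <- function(phi, pole_a, pole_b, from_vm = FALSE) {
  if (from_vm) (phi[, pole_b] - phi[, pole_a]) / 2
  else phi[, pole_a] - phi[, pole_b]
}

#' Conduction-velocity restitution of one mMS parameter set
#'
#' Runs the S1S2 protocol over the whole s2 ladder (drive train simulated
#' once, branched per s2), synthesises the two bipolar electrograms, and
#' measures, for each s2, the conduction velocity of the premature beat as
#' `pair_separation / (LAT2 - LAT1)`. LATs come from [detect_lat()] (first
#' electrogram extremum above 5% of the drive-train deflection amplitude).
#' The effective refractory period is the largest s2 at which the premature
#' beat fails to capture at the electrode; CVs below the ERP are absent.
#'
#' @inheritParams run_cable
#' @return An object of class `cv_restitution`: list with `s2` (ms,
#'   descending), `cv` (cm/s, `NA` where absent), `captured` (logical),
#'   `erp` (ms; `NA` if capture never failed).
#' @export
restitution_curve <- function(p, D, cfg = cable_config(preset = "desk"),
                              protocol = pacing_protocol()) {
  poles <- cable_pole_nodes(cfg)
  ladder <- s2_ladder(protocol)
  drive <- protocol$s1 * (seq_len(protocol$n_s1) - 1)
  t_last <- drive[length(drive)]
  branch_asc <- sort(t_last + ladder)            # ascending for checkpointing
  post <- cable_post_window(p, D, cfg)
  res <- cable_ladder_cpp(
    tau = c(p$tau_in, p$tau_out, p$tau_open, p$tau_close),
    vgate = p$v_gate, D = D,
    n_nodes = poles$n_nodes, dx_cm = cfg$dx_um * 1e-4,
    dt_ode_ms = cfg$dt_ode_us * 1e-3, dt_pde_ms = cfg$dt_pde_us * 1e-3,
    stim_len_cm = cfg$stim_length_mm / 10,
    stim_amp = cfg$stim_amplitude, stim_dur_ms = cfg$stim_duration_ms,
    drive_times = drive, branch_times = branch_asc,
    post_ms = post, sample_idx0 = poles$idx0)

  # On the cable the propagation direction is known (poles ordered away
  # from the stimulus), so a depolarisation front passing pole a before
  # pole b deflects the bipolar trace (vm_b - vm_a)/2 valley-first, while
  # the preceding beat's repolarisation deflects it peak-first. Valley-only
  # detection therefore annotates the activation wave and rejects the
  # repolarisation hump regardless of its amplitude. The capture threshold
  # is 5% of the drive train's valley depth at the same pair.
  trunk <- res$trunk
  pair_trace <- function(time, vm, pair)
    data.frame(time_ms = time,
               value = bipolar_signal(vm, 2 * pair - 1, 2 * pair,
                                      from_vm = TRUE))
  ref_amp <- vapply(1:2, function(pair)
    max(-pair_trace(trunk$time, trunk$vm, pair)$value, 0), numeric(1))
  thresh <- 0.05 * ref_amp

  n <- length(ladder)
  cv <- rep(NA_real_, n)
  captured <- logical(n)
  for (i in seq_len(n)) {
    s2 <- ladder[i]
    k <- match(t_last + s2, branch_asc)
    br <- res$branches[[k]]
    lat <- numeric(2)
    for (pair in 1:2) {
      tr <- pair_trace(br$time, br$vm, pair)
      lat0 <- detect_lat(tr, window = c(t_last + s2 + 2, max(br$time)),
                         threshold = thresh[pair],
                         polarity = "negative")
      # refine to sub-sample resolution at the leading edge (half-depth
      # crossing of the annotated valley): pair CVs over 7 mm would
      # otherwise be quantised by the PDE output step
      if (is.finite(lat0)) {
        j <- which(tr$time_ms >= lat0 - 1e-9)[1]
        half <- tr$value[j] / 2
        while (j > 1 && tr$value[j - 1] <= half) j <- j - 1
        if (j > 1) {
          f <- (half - tr$value[j - 1]) / (tr$value[j] - tr$value[j - 1])
          lat0 <- tr$time_ms[j - 1] + f * (tr$time_ms[j] - tr$time_ms[j - 1])
        }
      }
      lat[pair] <- lat0
    }
    captured[i] <- is.finite(lat[1]) && ref_amp[1] > 1e-9
    if (all(is.finite(lat)) && lat[2] > lat[1])
      cv[i] <- cfg$pair_separation_mm / 10 / (lat[2] - lat[1]) * 1000  # cm/s
  }
  erp <- if (any(!captured)) max(ladder[!captured]) else NA_real_
  if (!any(captured)) erp <- protocol$s2_start
  if (is.finite(erp)) cv[ladder <= erp] <- NA_real_
  structure(list(s2 = ladder, cv = cv, captured = captured, erp = erp),
            class = "cv_restitution")
}

#' @export
print.cv_restitution <- function(x, ...) {
  n_cap <- sum(x$captured)
  cat(sprintf("CV restitution: %d s2 values (%g..%g ms), %d captured, ERP = %s ms\n",
              length(x$s2), max(x$s2), min(x$s2), n_cap,
              ifelse(is.finite(x$erp), format(x$erp, digits = 4), "< ladder")))
  invisible(x)
}

#' Write a trace to CSV (time_ms, value)
#'
#' @param trace Data frame with columns `time_ms` and `value`.
#' @param path Output file.
#' @export
write_trace_csv <- function(trace, path) {
  utils::write.csv(trace[, c("time_ms", "value")], path, row.names = FALSE)
}

#' Read cable/protocol configuration from YAML
#'
#' The YAML keys mirror the [cable_config()] and [pacing_protocol()]
#' argument names under top-level `cable:` and `protocol:` sections (either
#' may be omitted).
#'
#' @param path YAML file.
#' @return List with elements `cable` and `protocol`.
#' @export
config_from_yaml <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read YAML configs", call. = FALSE)
  y <- yaml::read_yaml(path)
  list(cable = do.call(cable_config, as.list(y$cable %||% list())),
       protocol = do.call(pacing_protocol, as.list(y$protocol %||% list())))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
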