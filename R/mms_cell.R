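# Modified Mitchell-Schaeffer (mMS) two-variable cell model: right-hand side,
# leading-order physiological markers, and the exact algebraic inversion from
# markers back to model parameters. Everything is dimensionless in voltage
# (rest 0, plateau ~1); time constants are in ms, diffusion in cm^2/ms.

#' mMS model parameters
#'
#' Container for the four characteristic time constants of the modified
#' Mitchell-Schaeffer action-potential model plus the (fixed) gate threshold.
#' The mMS reaction term is
#' \deqn{I_{ion} = h\,v_m(v_m - v_{gate})(1 - v_m)/\tau_{in} - v_m/\tau_{out},}
#' which, unlike the classical Mitchell-Schaeffer model, has a stable resting
#' state at \eqn{v_m = 0} for every admissible parameter combination (no
#' pacemaker behaviour).
#'
#' @param tau_in Inward (depolarisation) time constant, ms.
#' @param tau_out Outward (repolarisation) time constant, ms. Must exceed
#'   `tau_in` for a propagating, repolarising action potential.
#' @param tau_open Gate recovery time constant, ms.
#' @param tau_close Gate closing time constant, ms; sets action potential
#'   duration.
#' @param v_gate Dimensionless gate threshold, default 0.1.
#' @return An object of class `mms_params`.
#' @examples
#' p <- mms_params(tau_in = 0.3, tau_out = 6, tau_open = 120, tau_close = 150)
#' @export
mms_params <- function(tau_in, tau_out, tau_open, tau_close, v_gate = 0.1) {
  vals <- c(tau_in = tau_in, tau_out = tau_out,
            tau_open = tau_open, tau_close = tau_close)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all mMS time constants must be finite and > 0", call. = FALSE)
  if (!is.finite(v_gate) || v_gate <= 0 || v_gate >= 0.5)
    stop("v_gate must lie in (0, 0.5)", call. = FALSE)
  if (tau_in >= tau_out)
    stop("tau_in must be smaller than tau_out (h_min < 1 requires it)",
         call. = FALSE)
  structure(list(tau_in = tau_in, tau_out = tau_out, tau_open = tau_open,
                 tau_close = tau_close, v_gate = v_gate),
            class = "mms_params")
}

#' @export
print.mms_params <- function(x, ...) {
  cat("mMS cell parameters:\n")
  cat(sprintf("  tau_in  = %g ms   tau_out   = %g ms\n", x$tau_in, x$tau_out))
  cat(sprintf("  tau_open= %g ms   tau_close = %g ms\n", x$tau_open, x$tau_close))
  cat(sprintf("  v_gate  = %g (dimensionless)\n", x$v_gate))
  invisible(x)
}

#' Physiological cell markers
#'
#' The five observable quantities spanning the restitution-database grid:
#' maximum conduction velocity, maximum action potential duration, the
#' minimum of the gate null-cline, and the `tau_in` / `tau_open` ionic
#' constants carried through unchanged.
#'
#' @param cv_max Maximum (fully rested) conduction velocity, cm/s.
#' @param apd_max Maximum action potential duration, ms.
#' @param h_min Minimum of the gate variable on the null-cline, in (0, 1).
#' @param tau_in Inward time constant, ms.
#' @param tau_open Gate recovery time constant, ms.
#' @return An object of class `cell_markers`.
#' @export
cell_markers <- function(cv_max, apd_max, h_min, tau_in, tau_open) {
  vals <- c(cv_max = cv_max, apd_max = apd_max, h_min = h_min,
            tau_in = tau_in, tau_open = tau_open)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all cell markers must be finite and > 0", call. = FALSE)
  if (h_min >= 1)
    stop("h_min must be < 1 (no repolarised propagation otherwise)",
         call. = FALSE)
  structure(as.list(vals), class = "cell_markers")
}

#' @export
print.cell_markers <- function(x, ...) {
  cat(sprintf(
    "cell markers: CVmax = %g cm/s, APDmax = %g ms, hmin = %g, tau_in = %g ms, tau_open = %g ms\n",
    x$cv_max, x$apd_max, x$h_min, x$tau_in, x$tau_open))
  invisible(x)
}

#' mMS ionic current (reaction rate of the transmembrane potential)
#'
#' Pure function of state; vectorised over `vm` and `h`. At rest
#' (`vm = 0`) the rate is exactly zero and for any `0 < vm < v_gate` it is
#' strictly negative, so the resting point cannot self-excite.
#'
#' @param vm Transmembrane potential (dimensionless).
#' @param h Gate variable in \[0, 1\].
#' @param p An [mms_params()] object.
#' @return Rate dvm/dt in 1/ms.
#' @export
ionic_current <- function(vm, h, p) {
  h * vm * (vm - p$v_gate) * (1 - vm) / p$tau_in - vm / p$tau_out
}

#' mMS gate dynamics
#'
#' `dh/dt = (1 - h)/tau_open` while `vm < v_gate` (recovery), and
#' `-h/tau_close` otherwise (closing). Keeps `h` inside \[0, 1\] for any
#' forward-Euler step smaller than `min(tau_open, tau_close)`.
#'
#' @inheritParams ionic_current
#' @return Rate dh/dt in 1/ms.
#' @export
gate_rate <- function(vm, h, p) {
  ifelse(vm < p$v_gate, (1 - h) / p$tau_open, -h / p$tau_close)
}

#' Unstimulated 0D time integration of the mMS model
#'
#' Forward-Euler integration of a single cell from an initial state, used to
#' probe stability of the resting point and gate boundedness.
#'
#' @param p An [mms_params()] object.
#' @param vm0,h0 Initial state.
#' @param dt Time step, ms.
#' @param t_end End time, ms.
#' @return A list with vectors `time`, `vm`, `h`.
#' @export
integrate_cell <- function(p, vm0, h0, dt = 0.01, t_end = 500) {
  n <- floor(t_end / dt)
  vm <- numeric(n + 1); hh <- numeric(n + 1)
  vm[1] <- vm0; hh[1] <- h0
  for (i in seq_len(n)) {
    vm[i + 1] <- vm[i] + dt * ionic_current(vm[i], hh[i], p)
    hh[i + 1] <- hh[i] + dt * gate_rate(vm[i], hh[i], p)
  }
  list(time = dt * (0:n), vm = vm, h = hh)
}

#' Leading-order physiological markers of an mMS parameter set
#'
#' Closed-form leading-order expressions linking the mMS constants and the
#' diffusion coefficient to observable markers:
#' \deqn{h_{min} = \frac{4\tau_{in}}{\tau_{out}(1-v_{gate})^2},\qquad
#'       APD_{max} = \tau_{close}\ln(1/h_{min}),\qquad
#'       CV_{max} = \kappa(h_{min}, v_{gate})\sqrt{D/(2\tau_{in})}.}
#'
#' The CV marker is referenced to the pacing protocol: it is the front
#' speed of the premature beat at the longest tested coupling interval
#' (`s2_ref`, default 343 ms) — the fastest conduction velocity the
#' clinical protocol observes. For a partially recovered gate `h` the
#' linear outward current `-v/tau_out` shifts the roots of the cubic
#' reaction to
#' \eqn{v_\pm = [(1+v_{gate}) \pm (1-v_{gate})\sqrt{1-h_{min}/h}]/2},
#' and the exact front speed of the fast subsystem is
#' \deqn{CV = \sqrt{\frac{D\,h}{2\tau_{in}}}\;\kappa(h_{min}/h),\qquad
#'   \kappa(x) = \tfrac{1}{2}\left[3(1-v_{gate})\sqrt{1-x} -
#'   (1+v_{gate})\right],}
#' which reduces to the textbook `(1-2 v_gate) sqrt(D/(2 tau_in))` for a
#' fully recovered gate and vanishing `h_min`. The gate level `h` at the
#' premature beat follows from the leading-order drive-train dynamics:
#' the drive beat's APD is `tau_close log(h_s1/h_min)` with
#' `h_s1 = 1 - (1-h_min) exp(-(s1 - apd_max)/tau_open)`, and `h` recovers
#' over the diastolic interval `s2_ref - APD_s1`. `CV_max` is returned in
#' cm/s (`D` in cm^2/ms, times in ms).
#'
#' @param p An [mms_params()] object.
#' @param D Diffusion coefficient, cm^2/ms.
#' @param s1_ref,s2_ref Protocol reference intervals, ms (defaults 470 and
#'   343, the clinical S1S2 protocol).
#' @return A [cell_markers()] object.
#' @export
leading_order_markers <- function(p, D, s1_ref = 470, s2_ref = 343) {
  if (!is.finite(D) || D <= 0) stop("D must be finite and > 0", call. = FALSE)
  h_min <- 4 * p$tau_in / (p$tau_out * (1 - p$v_gate)^2)
  if (h_min >= 1)
    stop("tau_out <= 4*tau_in/(1 - v_gate)^2: h_min >= 1, no repolarised propagation",
         call. = FALSE)
  apd_max <- p$tau_close * log(1 / h_min)
  h1 <- gate_at_premature(h_min, apd_max, p$tau_open, p$tau_close,
                          s1_ref, s2_ref)
  kap <- cv_prefactor(h_min / h1, p$v_gate)
  cv_max <- kap * sqrt(D * h1 / (2 * p$tau_in)) * 1000  # cm/ms -> cm/s
  cell_markers(cv_max = cv_max, apd_max = apd_max, h_min = h_min,
               tau_in = p$tau_in, tau_open = p$tau_open)
}

# front-speed prefactor; positive only while the excited root exceeds
# twice the threshold root (x = h_min / h)
cv_prefactor <- function(x, v_gate) {
  kap <- 0.5 * (3 * (1 - v_gate) * sqrt(1 - x) - (1 + v_gate))
  if (any(!is.finite(kap)) || any(kap <= 0))
    stop("effective h_min too large for propagation at this v_gate ",
         "(CV prefactor non-positive)", call. = FALSE)
  kap
}

# leading-order gate level immediately before the premature beat of the
# reference S1S2 protocol
gate_at_premature <- function(h_min, apd_max, tau_open, tau_close,
                              s1_ref, s2_ref) {
  h_s1 <- 1 - (1 - h_min) * exp(-max(s1_ref - apd_max, 0) / tau_open)
  apd_s1 <- tau_close * log(h_s1 / h_min)
  di <- s2_ref - apd_s1
  if (di <= 0)
    stop("premature interval shorter than the leading-order drive APD: ",
         "no recovery at s2_ref", call. = FALSE)
  1 - (1 - h_min) * exp(-di / tau_open)
}

#' Invert cell markers to mMS parameters and diffusion
#'
#' Exact algebraic inverse of [leading_order_markers()]:
#' `tau_out = 4 tau_in / (h_min (1-v_gate)^2)`,
#' `tau_close = apd_max / ln(1/h_min)`, and
#' `D = 2 tau_in (cv_max / kappa)^2 / h1` with `kappa` and `h1` the
#' protocol-referenced front-speed prefactor and premature-beat gate level
#' of [leading_order_markers()] (cv_max converted cm/s to cm/ms);
#' `tau_in` and `tau_open` are carried through. Rows whose leading-order
#' gate cannot sustain propagation at the reference coupling (prefactor
#' non-positive, or drive APD exceeding `s2_ref`) are rejected with an
#' error, which the database build records as an infeasible row.
#'
#' @param m A [cell_markers()] object.
#' @param v_gate Gate threshold, default 0.1.
#' @param s1_ref,s2_ref Protocol reference intervals, ms.
#' @return A list with elements `params` ([mms_params()]) and `D` (cm^2/ms).
#' @export
invert_markers <- function(m, v_gate = 0.1, s1_ref = 470, s2_ref = 343) {
  if (!inherits(m, "cell_markers")) m <- do.call(cell_markers, as.list(m))
  tau_out <- 4 * m$tau_in / (m$h_min * (1 - v_gate)^2)
  tau_close <- m$apd_max / log(1 / m$h_min)
  h1 <- gate_at_premature(m$h_min, m$apd_max, m$tau_open, tau_close,
                          s1_ref, s2_ref)
  kap <- cv_prefactor(m$h_min / h1, v_gate)
  D <- 2 * m$tau_in * (m$cv_max / 1000 / kap)^2 / h1
  list(params = mms_params(tau_in = m$tau_in, tau_out = tau_out,
                           tau_open = m$tau_open, tau_close = tau_close,
                           v_gate = v_gate),
       D = D)
}

#' Serialise mMS parameters to JSON (units in field names)
#'
#' @param p An [mms_params()] object.
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @return JSON string (invisibly, if written to file).
#' @export
mms_params_to_json <- function(p, path = NULL) {
  x <- list(tau_in_ms = p$tau_in, tau_out_ms = p$tau_out,
            tau_open_ms = p$tau_open, tau_close_ms = p$tau_close,
            v_gate = p$v_gate)
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}

#' Read mMS parameters from JSON written by [mms_params_to_json()]
#'
#' @param path File path or JSON string.
#' @return An [mms_params()] object.
#' @export
mms_params_from_json <- function(path) {
  x <- jsonlite::fromJSON(path)
  mms_params(tau_in = x$tau_in_ms, tau_out = x$tau_out_ms,
             tau_open = x$tau_open_ms, tau_close = x$tau_close_ms,
             v_gate = x$v_gate)
}
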