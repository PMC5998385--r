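# Electrogram processing: local activation times from bipolar traces,
# piecewise-linear CV fields over a catheter snapshot, the physiological CV
# cut-off, and per-electrode ERP estimation. These are the inputs the
# fitting stage consumes.

#' Local activation time of a bipolar electrogram
#'
#' The LAT is the time of the first local extremum (peak or valley, whichever
#' comes first) of the trace inside the search window whose absolute value
#' exceeds the capture threshold. Returns `NA` when no such deflection
#' exists (no capture).
#'
#' @param trace Data frame with columns `time_ms`, `value`, time-sorted.
#' @param window Length-2 numeric, search window in ms (inclusive).
#' @param threshold Minimum absolute deflection counting as capture. The
#'   package convention is 5% of the drive-train deflection amplitude of
#'   the same electrode.
#' @param polarity `"both"` (default) accepts peaks and valleys;
#'   `"negative"`/`"positive"` restrict to valleys/peaks (useful when the
#'   propagation direction relative to the pole order is known, as in the
#'   1D cable).
#' @return Time in ms of the first qualifying extremum, or `NA_real_`.
#' @export
detect_lat <- function(trace, window = range(trace$time_ms), threshold = 0,
                       polarity = c("both", "negative", "positive")) {
  polarity <- match.arg(polarity)
  if (window[2] < window[1]) stop("empty search window", call. = FALSE)
  sel <- trace$time_ms >= window[1] & trace$time_ms <= window[2]
  if (!any(sel)) stop("search window outside the trace span", call. = FALSE)
  t <- trace$time_ms[sel]; v <- trace$value[sel]
  n <- length(v)
  if (n < 3) return(NA_real_)
  i <- 2:(n - 1)
  peak <- v[i] >= v[i - 1] & v[i] > v[i + 1]
  valley <- v[i] <= v[i - 1] & v[i] < v[i + 1]
  keep <- switch(polarity,
                 both = peak | valley,
                 negative = valley & v[i] < 0,
                 positive = peak & v[i] > 0)
  ext <- i[keep & abs(v[i]) >= threshold]
  if (!length(ext)) return(NA_real_)
  t[ext[1]]
}

#' High-pass conditioning of a synthetic electrogram
#'
#' Clinical bipolar electrograms are hardware high-pass filtered, which
#' suppresses the slow repolarisation deflection that the raw monodomain
#' surrogate `(vm_b - vm_a)/2` retains. This applies the discrete analogue
#' — a first difference scaled to a rate (per ms) — so that the sharp
#' depolarisation deflection dominates and [detect_lat()] picks the
#' activation wave, not the previous beat's repolarisation.
#'
#' @param trace Data frame with `time_ms`, `value`.
#' @return A conditioned trace (same columns; first sample is 0).
#' @export
condition_egm <- function(trace) {
  dt <- diff(trace$time_ms)
  data.frame(time_ms = trace$time_ms,
             value = c(0, diff(trace$value) / dt))
}

#' Piecewise-linear conduction-velocity field over a catheter snapshot
#'
#' Implements the standard LAT-gradient CV estimator: electrode positions
#' are projected onto their least-squares best-fit plane, the projected
#' points are Delaunay-triangulated, the (constant) LAT gradient is computed
#' per triangle, and the local speed is `1/|grad LAT|`. Each electrode is
#' then assigned the median of the triangle CVs whose centroid lies within
#' `radius_mm` of the electrode (in-plane distance); the default radius of
#' 2.5 cm (twice a catheter spline length) suppresses spurious values.
#'
#' @param positions n x 3 matrix of electrode positions, mm.
#' @param lats Length-n LATs in ms; `NA` marks electrodes without capture.
#' @param radius_mm Median-pooling radius, mm (default 25).
#' @return Length-n numeric vector of CVs in cm/s (`NA` where undefined).
#' @export
local_cv_field <- function(positions, lats, radius_mm = 25) {
  positions <- as.matrix(positions)
  n <- nrow(positions)
  ok <- which(is.finite(lats))
  out <- rep(NA_real_, n)
  if (length(ok) < 3) return(out)
  P <- positions[ok, , drop = FALSE]
  ctr <- colMeans(P)
  Pc <- sweep(P, 2, ctr)
  sv <- svd(Pc)
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1))
    stop("captured electrodes are collinear; CV field undefined", call. = FALSE)
  uv <- Pc %*% sv$v[, 1:2, drop = FALSE]
  tri <- delaunay2d(uv)
  lat_ok <- lats[ok]

  m <- nrow(tri)
  cv_tri <- rep(NA_real_, m)
  cen <- matrix(0, m, 2)
  for (k in seq_len(m)) {
    v <- tri[k, ]
    A <- rbind(uv[v[2], ] - uv[v[1], ], uv[v[3], ] - uv[v[1], ])
    b <- c(lat_ok[v[2]] - lat_ok[v[1]], lat_ok[v[3]] - lat_ok[v[1]])
    g <- tryCatch(solve(A, b), error = function(e) NULL)
    cen[k, ] <- colMeans(uv[v, ])
    if (is.null(g)) next
    gn <- sqrt(sum(g^2))                  # ms/mm
    if (gn > 1e-9) cv_tri[k] <- 1 / gn * 100  # mm/ms -> cm/s
  }
  for (j in seq_along(ok)) {
    d <- sqrt(rowSums(sweep(cen, 2, uv[j, ])^2))
    vals <- cv_tri[d <= radius_mm & is.finite(cv_tri)]
    if (length(vals)) out[ok[j]] <- stats::median(vals)
  }
  out
}

#' Remove CV values outside the physiological range
#'
#' Values above the cut-off (default 200 cm/s, the rounded mean + 2 SD of
#' pooled clinical left-atrial CV distributions) are marked absent; all
#' others pass unchanged.
#'
#' @param cv Numeric vector of CVs, cm/s.
#' @param cutoff Physiological upper bound, cm/s.
#' @return `cv` with out-of-range entries replaced by `NA`.
#' @export
filter_physiological <- function(cv, cutoff = 200) {
  cv[is.finite(cv) & cv > cutoff] <- NA_real_
  cv
}

#' Effective refractory period from per-s2 capture flags
#'
#' The ERP is the largest premature interval that failed to produce a local
#' activation. If capture never failed the ERP lies below the tested ladder
#' and `NA` is returned. A non-monotone capture pattern (loss of capture
#' followed by capture at a shorter s2) is physiologically unexpected; the
#' literal definition is still applied and a warning is emitted.
#'
#' @param s2 Numeric vector of tested s2 values, ms.
#' @param captured Logical vector aligned with `s2`.
#' @return ERP in ms, or `NA_real_` if all beats captured.
#' @export
estimate_erp <- function(s2, captured) {
  stopifnot(length(s2) == length(captured))
  if (all(captured)) return(NA_real_)
  o <- order(s2, decreasing = TRUE)
  cap <- captured[o]
  first_loss <- which(!cap)[1]
  if (any(cap[seq_along(cap) > first_loss]))
    warning("non-monotone capture pattern across the s2 ladder")
  max(s2[!captured])
}

#' Per-electrode CV restitution and ERP from a set of snapshot LATs
#'
#' Pipeline convenience: given per-electrode, per-s2 LATs and capture flags
#' for one catheter placement, computes the CV field at every s2
#' ([local_cv_field()]), applies the physiological cut-off, and estimates
#' the per-electrode ERP, yielding the measurement objects the fitting
#' stage consumes.
#'
#' @param positions n x 3 electrode positions, mm.
#' @param lat_matrix n x k matrix of LATs (ms), one column per s2; `NA` = no
#'   capture.
#' @param s2 Length-k vector of s2 values, ms.
#' @param cutoff Physiological CV cut-off, cm/s.
#' @param radius_mm Median-pooling radius for the CV field, mm.
#' @return A list of `cv_measurement` objects (one per electrode): fields
#'   `electrode`, `s2`, `cv`, `erp`.
#' @export
snapshot_measurements <- function(positions, lat_matrix, s2, cutoff = 200,
                                  radius_mm = 25) {
  positions <- as.matrix(positions)
  n <- nrow(positions)
  stopifnot(ncol(lat_matrix) == length(s2))
  cv <- matrix(NA_real_, n, length(s2))
  for (j in seq_along(s2)) {
    if (sum(is.finite(lat_matrix[, j])) >= 3) {
      cv[, j] <- tryCatch(
        filter_physiological(local_cv_field(positions, lat_matrix[, j],
                                            radius_mm), cutoff),
        error = function(e) rep(NA_real_, n))
    }
  }
  lapply(seq_len(n), function(i) {
    captured <- is.finite(lat_matrix[i, ])
    structure(list(electrode = i, s2 = s2, cv = cv[i, ],
                   erp = estimate_erp(s2, captured)),
              class = "cv_measurement")
  })
}

#' Read an electrode table from CSV
#'
#' Expected columns: `electrode_id`, `x_mm`, `y_mm`, `z_mm`, `s2_ms`,
#' `lat_ms` (empty/NA where no capture), `captured` (0/1 or logical).
#'
#' @param path CSV file.
#' @return Data frame with those columns, types coerced.
#' @export
read_electrode_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("electrode_id", "x_mm", "y_mm", "z_mm", "s2_ms", "lat_ms", "captured")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("electrode CSV missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  df$captured <- as.logical(df$captured)
  df
}

#' Write an electrode table to CSV
#'
#' @param df Data frame as returned by [read_electrode_csv()].
#' @param path Output file.
#' @export
write_electrode_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
}
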