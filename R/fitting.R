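# Per-electrode parameter estimation: least-squares match of measured CV
# restitution + ERP against the pre-computed database, with a second pass
# regularised toward the cohort (spatial) median of the fitted markers.

MARKER_NAMES <- c("cv_max", "tau_in", "h_min", "tau_open", "apd_max")

#' Fitting configuration
#'
#' Residuals are normalised so neither unit dominates: CV residuals by
#' `cv_scale` (default 200 cm/s, the physiological cut-off), the ERP
#' residual by the span of the s2 ladder, and marker penalties by the grid
#' range of each marker axis. `reg_lambda` weights the spatial-median
#' penalty; its default (0.1) is small enough that the penalty can only
#' flip a fit whose data terms are near-tied.
#'
#' @param erp_weight Weight of the squared normalised ERP residual
#'   (default 1). Set very large to approximate a hard ERP constraint.
#' @param reg_lambda Weight of the squared normalised marker-median
#'   penalty (default 0.1).
#' @param cv_scale CV normalisation, cm/s.
#' @param erp_scale ERP normalisation, ms; `NULL` = span of the database
#'   ladder at fit time.
#' @param marker_scales Named vector of per-marker normalisations; `NULL` =
#'   grid axis ranges of the database at fit time.
#' @return Object of class `fit_config`.
#' @export
fit_config <- function(erp_weight = 1, reg_lambda = 0.1, cv_scale = 200,
                       erp_scale = NULL, marker_scales = NULL) {
  if (erp_weight < 0 || reg_lambda < 0)
    stop("weights must be >= 0", call. = FALSE)
  structure(list(erp_weight = erp_weight, reg_lambda = reg_lambda,
                 cv_scale = cv_scale, erp_scale = erp_scale,
                 marker_scales = marker_scales),
            class = "fit_config")
}

# resolve data-dependent scales against a database
fit_scales <- function(cfg, db) {
  ladder <- attr(db, "s2")
  erp_scale <- cfg$erp_scale %||% max(max(ladder) - min(ladder), 1)
  ms <- cfg$marker_scales
  if (is.null(ms)) {
    grid <- attr(db, "grid")
    ms <- vapply(MARKER_NAMES, function(nm) {
      r <- diff(range(grid[[nm]]))
      if (r > 0) r else 1
    }, numeric(1))
  }
  list(erp_scale = erp_scale, marker_scales = ms)
}

# An ERP observed on a discrete s2 ladder is interval-censored: "no capture
# at s2 = a, capture at the next tested rung b" locates the refractory
# boundary in [a, b); capture at every tested rung locates it below the
# tested floor. Returns an n x 2 matrix of interval bounds.
erp_interval <- function(erp, tested_s2) {
  rungs <- sort(tested_s2)
  t(vapply(erp, function(e) {
    if (!is.finite(e)) return(c(0, min(rungs)))
    above <- rungs[rungs > e + 1e-9]
    c(e, if (length(above)) min(above) else e + min(rungs) * 0.02)
  }, numeric(2)))
}

# distance between two censoring intervals (zero when they overlap or touch)
interval_gap <- function(lo1, hi1, lo2, hi2) {
  pmax(0, lo1 - hi2, lo2 - hi1)
}

# vectorised cost over all database rows; returns matrix of term columns
fit_costs <- function(measured, db, cfg, medians = NULL) {
  ladder <- attr(db, "s2")
  sc <- fit_scales(cfg, db)
  idx <- match(round(measured$s2, 6), round(ladder, 6))
  use <- which(!is.na(idx) & is.finite(measured$cv))
  if (!length(use))
    stop("no overlapping s2 points between measurement and database",
         call. = FALSE)
  cvdb <- db_cv_matrix(db)[, idx[use], drop = FALSE]
  cvdb[!is.finite(cvdb)] <- 0  # a refractory row predicts no propagation
  resid <- sweep(cvdb, 2, measured$cv[use]) / cfg$cv_scale
  cv_term <- rowSums(resid^2)
  im <- erp_interval(measured$erp, measured$s2)
  idb <- erp_interval(db$erp, ladder)
  gap <- interval_gap(idb[, 1], idb[, 2], im[1], im[2])
  erp_term <- cfg$erp_weight * (gap / sc$erp_scale)^2
  pen_term <- 0
  if (!is.null(medians) && cfg$reg_lambda > 0) {
    M <- as.matrix(as.data.frame(db)[, MARKER_NAMES])
    dev <- sweep(sweep(M, 2, medians[MARKER_NAMES]), 2,
                 sc$marker_scales[MARKER_NAMES], "/")
    pen_term <- cfg$reg_lambda * rowSums(dev^2)
  }
  cbind(cv = cv_term, erp = erp_term, penalty = pen_term,
        total = cv_term + erp_term + pen_term)
}

#' Fitting cost of one database row against one measurement
#'
#' `cost = sum_s2 ((CV_meas - CV_row)/cv_scale)^2
#'        + erp_weight ((ERP_meas - ERP_row)/erp_scale)^2
#'        + reg_lambda sum_k ((marker_k - median_k)/scale_k)^2`,
#' with the penalty absent when no medians are supplied. The sum runs over
#' ladder steps with a measured CV; a row that is refractory at such a step
#' contributes its full measured CV as residual (the row predicts no
#' propagating beat there). ERPs observed on a discrete ladder are
#' interval-censored (the refractory boundary lies between the largest
#' non-capturing rung and the next tested rung, or below the tested
#' floor); the ERP residual is the gap between the measurement's and the
#' row's censoring intervals, zero whenever they overlap.
#'
#' @param measured A `cv_measurement` (fields `s2`, `cv`, `erp`).
#' @param db A `restitution_db`.
#' @param row Row index into `db`.
#' @param cfg A [fit_config()].
#' @param medians Optional named marker medians enabling the penalty term.
#' @return Named numeric: `cv`, `erp`, `penalty`, `total`.
#' @export
fit_cost <- function(measured, db, row, cfg = fit_config(), medians = NULL) {
  fit_costs(measured, db[row, , drop = FALSE] |> copy_db_attrs(db), cfg,
            medians)[1, ]
}

copy_db_attrs <- function(x, db) {
  for (a in c("s2", "grid", "cable", "protocol", "schema"))
    attr(x, a) <- attr(db, a)
  class(x) <- class(db)
  x
}

#' Fit all electrodes against the database with median regularisation
#'
#' Two passes: (1) per-electrode argmin of the unregularised cost;
#' (2) marker medians over the pass-1 winners define a penalty pulling each
#' electrode toward the cohort, and the argmin is recomputed. Ties break
#' deterministically to the lowest database row index. Electrode order does
#' not affect the result.
#'
#' @param measurements List of `cv_measurement` objects.
#' @param db A `restitution_db`.
#' @param cfg A [fit_config()].
#' @return List of `fit_result` objects: `electrode`, `markers`
#'   ([cell_markers()]), `params` ([mms_params()]), `D`, `row` (database row
#'   index), `row_pass1`, `cost` (named terms), `runner_up_gap`.
#' @export
fit_all <- function(measurements, db, cfg = fit_config()) {
  if (!length(measurements)) stop("no measurements supplied", call. = FALSE)
  feasible <- which(db$ok)
  if (!length(feasible)) stop("database has no feasible rows", call. = FALSE)
  dbf <- copy_db_attrs(as.data.frame(db)[feasible, , drop = FALSE], db)

  pick <- function(medians) {
    lapply(measurements, function(m) {
      costs <- fit_costs(m, dbf, cfg, medians)
      j <- which.min(costs[, "total"])
      gap <- if (nrow(costs) > 1)
        sort(costs[, "total"], partial = 2)[2] - costs[j, "total"] else NA_real_
      list(j = j, cost = costs[j, ], gap = gap)
    })
  }

  pass1 <- pick(NULL)
  winners <- vapply(pass1, function(x) x$j, integer(1))
  med <- vapply(MARKER_NAMES, function(nm)
    stats::median(dbf[[nm]][winners]), numeric(1))
  pass2 <- if (cfg$reg_lambda > 0) pick(med) else pass1

  lapply(seq_along(measurements), function(i) {
    j <- pass2[[i]]$j
    row <- dbf[j, ]
    mk <- cell_markers(cv_max = row$cv_max, apd_max = row$apd_max,
                       h_min = row$h_min, tau_in = row$tau_in,
                       tau_open = row$tau_open)
    structure(list(
      electrode = measurements[[i]]$electrode %||% i,
      markers = mk,
      params = mms_params(tau_in = row$tau_in, tau_out = row$tau_out,
                          tau_open = row$tau_open, tau_close = row$tau_close),
      D = row$D,
      row = feasible[j], row_pass1 = feasible[winners[i]],
      cost = pass2[[i]]$cost, runner_up_gap = pass2[[i]]$gap,
      medians = med),
      class = "fit_result")
  })
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("fit (electrode %s): CVmax = %g cm/s, APDmax = %g ms, hmin = %g; cost = %.4g\n",
              format(x$electrode), x$markers$cv_max, x$markers$apd_max,
              x$markers$h_min, x$cost[["total"]]))
  invisible(x)
}

#' Export fitted parameters as a per-electrode table
#'
#' @param fits List of `fit_result` objects.
#' @return Data frame, one row per electrode, with markers, mMS parameters
#'   and diffusion.
#' @export
fits_to_table <- function(fits) {
  do.call(rbind, lapply(fits, function(f) {
    data.frame(electrode = f$electrode, cv_max = f$markers$cv_max,
               apd_max = f$markers$apd_max, h_min = f$markers$h_min,
               tau_in = f$params$tau_in, tau_out = f$params$tau_out,
               tau_open = f$params$tau_open, tau_close = f$params$tau_close,
               D = f$D, cost = unname(f$cost[["total"]]))
  }))
}
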