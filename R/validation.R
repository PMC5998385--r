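# Agreement indices between measured and simulated LATs: regression line,
# Pearson correlation, covariance slender ratio and functional-block error,
# pooled over electrodes and coupling intervals.

drop_incomplete <- function(measured, computed) {
  ok <- is.finite(measured) & is.finite(computed)
  list(x = measured[ok], y = computed[ok], n = sum(ok))
}

#' Regression line of computed on measured LATs
#'
#' Ordinary least squares `y = m x + q` with measured on x and computed on
#' y; a perfect model has slope 1 and intercept 0.
#'
#' @param measured,computed Numeric vectors, ms; incomplete pairs dropped.
#' @return Named numeric `c(q, m)` (intercept ms, slope dimensionless).
#' @export
regression_line <- function(measured, computed) {
  d <- drop_incomplete(measured, computed)
  if (d$n < 2) stop("need at least 2 complete pairs", call. = FALSE)
  if (stats::var(d$x) == 0)
    stop("zero variance in measured LATs", call. = FALSE)
  fit <- stats::lm.fit(cbind(1, d$x), d$y)
  c(q = unname(fit$coefficients[1]), m = unname(fit$coefficients[2]))
}

#' Pearson correlation between measured and computed LATs
#'
#' @inheritParams regression_line
#' @return Correlation coefficient in \[-1, 1\].
#' @export
pearson_r <- function(measured, computed) {
  d <- drop_incomplete(measured, computed)
  if (d$n < 2) stop("need at least 2 complete pairs", call. = FALSE)
  if (stats::var(d$x) == 0 || stats::var(d$y) == 0)
    stop("zero variance; correlation undefined", call. = FALSE)
  stats::cor(d$x, d$y)
}

#' Covariance slender ratio
#'
#' Ratio of the minor to the major principal component (eigenvalue) of the
#' 2 x 2 covariance matrix of (measured, computed): 0 for perfectly
#' collinear agreement, approaching 1 for isotropic scatter. Invariant
#' under rotations of the plane.
#'
#' @inheritParams regression_line
#' @return Slender ratio in \[0, 1\].
#' @export
slender_ratio <- function(measured, computed) {
  d <- drop_incomplete(measured, computed)
  if (d$n < 3) stop("need at least 3 complete pairs", call. = FALSE)
  ev <- eigen(stats::cov(cbind(d$x, d$y)), symmetric = TRUE,
              only.values = TRUE)$values
  if (ev[1] <= 0) return(0)
  max(ev[2], 0) / ev[1]
}

#' Functional-block error
#'
#' `100 * sum(blocked) / sum(measured)`: the number of electrode
#' observations at which the simulation blocked (no activation), summed
#' over coupling intervals, relative to the total number of measured LATs.
#'
#' @param n_blocked Integer vector, blocked electrode count per s2.
#' @param n_measured Integer vector, measured LAT count per s2.
#' @return Percentage in \[0, 100\].
#' @export
fblock_error <- function(n_blocked, n_measured) {
  if (sum(n_measured) <= 0) stop("no measured LATs", call. = FALSE)
  100 * sum(n_blocked) / sum(n_measured)
}

#' Full validation report for one pacing site
#'
#' Pools (electrode, s2) LAT pairs, applies one global mean-offset
#' correction ([offset_correct()]), and computes the four agreement
#' indices. Pairs where the simulation blocked are excluded from the
#' regression/correlation indices and counted in the functional-block
#' error instead.
#'
#' @param measured,computed Matrices (electrodes x s2) or vectors of LATs,
#'   ms; `NA` in `measured` = not measured, `NA` in `computed` = blocked.
#' @param s2 Optional s2 values labelling the columns.
#' @param apply_offset Apply the global mean-offset correction first
#'   (default TRUE).
#' @return Object of class `validation_report`: `q`, `m`, `r`, `sl`,
#'   `fblock_error`, `n_pairs`, `offset`, `per_s2` (data frame), and the
#'   paired vectors used.
#' @export
validation_report <- function(measured, computed, s2 = NULL,
                              apply_offset = TRUE) {
  measured <- as.matrix(measured); computed <- as.matrix(computed)
  stopifnot(identical(dim(measured), dim(computed)))
  meas_mask <- is.finite(measured)
  blocked_mask <- meas_mask & !is.finite(computed)

  mv <- measured[meas_mask & !blocked_mask]
  cv <- computed[meas_mask & !blocked_mask]
  off <- 0
  if (apply_offset && length(mv)) {
    cv <- offset_correct(cv, mv)
    off <- attr(cv, "offset")
  }
  qm <- regression_line(mv, cv)
  per_s2 <- data.frame(
    s2 = if (is.null(s2)) seq_len(ncol(measured)) else s2,
    n_measured = colSums(meas_mask),
    n_blocked = colSums(blocked_mask))
  structure(list(q = qm[["q"]], m = qm[["m"]],
                 r = pearson_r(mv, cv),
                 sl = slender_ratio(mv, cv),
                 fblock_error = fblock_error(per_s2$n_blocked,
                                             per_s2$n_measured),
                 n_pairs = length(mv), offset = off, per_s2 = per_s2,
                 measured = mv, computed = as.numeric(cv)),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("validation: (q, m) = (%.2f, %.2f), r = %.3f, sl = %.3f, fblock = %.2f%% (n = %d)\n",
              x$q, x$m, x$r, x$sl, x$fblock_error, x$n_pairs))
  invisible(x)
}

#' Write a validation report to JSON (+ optional scatter CSV)
#'
#' @param report A `validation_report`.
#' @param path JSON output file.
#' @param scatter_csv Optional CSV of the (measured, computed) pairs.
#' @export
write_validation_report <- function(report, path, scatter_csv = NULL) {
  out <- report[c("q", "m", "r", "sl", "fblock_error", "n_pairs", "offset")]
  out$per_s2 <- report$per_s2
  writeLines(jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA,
                              dataframe = "columns"), path)
  if (!is.null(scatter_csv))
    utils::write.csv(data.frame(measured_ms = report$measured,
                                computed_ms = report$computed),
                     scatter_csv, row.names = FALSE)
  invisible(path)
}
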