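# The pre-computed restitution database: the marker grid, its enumeration,
# the simulation build (1D cable per marker tuple) and lossless CSV+JSON
# persistence.

#' The marker grid spanning the restitution database
#'
#' Default axes reproduce the published sweep: CVmax 10..300 by 10 cm/s
#' (30 values), tau_in 0.01..0.31 by 0.03 ms (11), h_min
#' \{0.01..0.09 by 0.02\} U \{0.1..0.5 by 0.1\} (10), tau_open 65..215 by
#' 10 ms (16), APDmax 120..270 by 15 ms (11) — a Cartesian product of
#' 580,800 combinations.
#'
#' @param cv_max,tau_in,h_min,tau_open,apd_max Numeric vectors of axis
#'   values (defaults as above).
#' @return An object of class `marker_grid`.
#' @export
marker_grid <- function(cv_max = seq(10, 300, by = 10),
                        tau_in = seq(0.01, 0.31, by = 0.03),
                        h_min = c(seq(0.01, 0.09, by = 0.02),
                                  seq(0.1, 0.5, by = 0.1)),
                        tau_open = seq(65, 215, by = 10),
                        apd_max = seq(120, 270, by = 15)) {
  axes <- list(cv_max = cv_max, tau_in = tau_in, h_min = h_min,
               tau_open = tau_open, apd_max = apd_max)
  for (nm in names(axes)) {
    v <- axes[[nm]]
    if (!length(v) || any(!is.finite(v)) || any(v <= 0) || is.unsorted(v))
      stop("axis ", nm, " must be a sorted positive vector", call. = FALSE)
  }
  if (any(axes$h_min >= 1)) stop("h_min values must be < 1", call. = FALSE)
  structure(axes, class = "marker_grid")
}

#' @export
print.marker_grid <- function(x, ...) {
  counts <- vapply(x, length, integer(1))
  cat("marker grid:", paste(sprintf("%s[%d]", names(counts), counts),
                            collapse = " x "),
      "=", format(prod(counts), big.mark = ","), "combinations\n")
  invisible(x)
}

#' Enumerate every marker combination of a grid
#'
#' Deterministic lexicographic order with `cv_max` most significant and
#' `apd_max` least significant. The default grid enumerates 580,800 rows.
#'
#' @param spec A [marker_grid()] object.
#' @return Data frame with columns `cv_max`, `tau_in`, `h_min`, `tau_open`,
#'   `apd_max`, one row per combination.
#' @export
enumerate_grid <- function(spec = marker_grid()) {
  g <- expand.grid(apd_max = spec$apd_max, tau_open = spec$tau_open,
                   h_min = spec$h_min, tau_in = spec$tau_in,
                   cv_max = spec$cv_max, KEEP.OUT.ATTRS = FALSE)
  g[, c("cv_max", "tau_in", "h_min", "tau_open", "apd_max")]
}

#' Build a restitution database by simulating the pacing protocol
#'
#' For each marker tuple, the markers are inverted to mMS parameters plus a
#' diffusion coefficient ([invert_markers()]) and the 1D cable S1S2 protocol
#' is simulated ([restitution_curve()]). Rows whose simulation fails (e.g.
#' solver instability at extreme parameter corners) are flagged and the
#' build continues. The build is deterministic: no randomness enters the
#' simulation, so identical configurations reproduce identical databases.
#'
#' The full published grid is a cluster-scale computation; `stride` (keep
#' every k-th row of the enumeration) or an explicit `rows` index provides
#' the documented desk-scale subsampling.
#'
#' @param spec A [marker_grid()].
#' @param cfg A [cable_config()]; the desk preset is the default.
#' @param protocol A [pacing_protocol()].
#' @param stride Keep every `stride`-th row of the enumeration (default 1 =
#'   all rows).
#' @param rows Optional integer vector of enumeration rows to build
#'   (overrides `stride`).
#' @param v_gate Gate threshold used in the inversion.
#' @param verbose Print progress every 50 rows.
#' @return An object of class `restitution_db`: a data frame with marker,
#'   parameter, `D`, `erp`, `ok` columns and one `cv_<k>` column per ladder
#'   step; attributes `s2` (the ladder), `grid`, `cable`, `protocol`,
#'   `schema`.
#' @export
build_database <- function(spec = marker_grid(), cfg = cable_config(preset = "desk"),
                           protocol = pacing_protocol(), stride = 1L,
                           rows = NULL, v_gate = 0.1, verbose = FALSE) {
  g <- enumerate_grid(spec)
  if (is.null(rows)) rows <- seq(1, nrow(g), by = max(1L, as.integer(stride)))
  g <- g[rows, , drop = FALSE]
  ladder <- s2_ladder(protocol)
  n <- nrow(g); k <- length(ladder)
  cvm <- matrix(NA_real_, n, k)
  erp <- rep(NA_real_, n); ok <- rep(TRUE, n)
  # tau_in and tau_open are already marker columns; only the derived
  # parameters are stored alongside
  pars <- matrix(NA_real_, n, 3,
                 dimnames = list(NULL, c("tau_out", "tau_close", "D")))
  for (i in seq_len(n)) {
    m <- tryCatch(cell_markers(cv_max = g$cv_max[i], apd_max = g$apd_max[i],
                               h_min = g$h_min[i], tau_in = g$tau_in[i],
                               tau_open = g$tau_open[i]),
                  error = function(e) NULL)
    if (is.null(m)) { ok[i] <- FALSE; next }
    inv <- tryCatch(invert_markers(m, v_gate), error = function(e) NULL)
    if (is.null(inv)) { ok[i] <- FALSE; next }
    p <- inv$params
    pars[i, ] <- c(p$tau_out, p$tau_close, inv$D)
    curve <- tryCatch(restitution_curve(p, inv$D, cfg, protocol),
                      error = function(e) NULL)
    if (is.null(curve)) { ok[i] <- FALSE; next }
    cvm[i, ] <- curve$cv
    erp[i] <- curve$erp
    if (verbose && i %% 50 == 0)
      message(sprintf("built %d / %d rows", i, n))
  }
  db <- cbind(g, as.data.frame(pars), erp = erp, ok = ok,
              as.data.frame(cvm, col.names = paste0("cv_", seq_len(k))))
  names(db)[(ncol(db) - k + 1):ncol(db)] <- paste0("cv_", seq_len(k))
  rownames(db) <- NULL
  structure(db, s2 = ladder, grid = unclass(spec),
            cable = unclass(cfg), protocol = unclass(protocol),
            schema = "atriafit-db-1", row_index = rows,
            class = c("restitution_db", "data.frame"))
}

#' Save a restitution database (CSV table + JSON metadata sidecar)
#'
#' @param db A `restitution_db`.
#' @param path Output path stem; writes `<path>.csv` and `<path>.json`.
#' @return `path`, invisibly.
#' @export
save_db <- function(db, path) {
  utils::write.csv(as.data.frame(db), paste0(path, ".csv"), row.names = FALSE)
  meta <- list(schema = attr(db, "schema"), s2 = attr(db, "s2"),
               grid = attr(db, "grid"), cable = attr(db, "cable"),
               protocol = attr(db, "protocol"),
               row_index = attr(db, "row_index"), n_rows = nrow(db))
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA),
             paste0(path, ".json"))
  invisible(path)
}

#' Load a restitution database written by [save_db()]
#'
#' @param path Path stem used at save time.
#' @return A `restitution_db` object.
#' @export
load_db <- function(path) {
  meta_file <- paste0(path, ".json"); csv_file <- paste0(path, ".csv")
  if (!file.exists(meta_file) || !file.exists(csv_file))
    stop("database files not found at ", path, call. = FALSE)
  meta <- jsonlite::fromJSON(meta_file)
  if (!identical(meta$schema, "atriafit-db-1"))
    stop("unsupported database schema: ", meta$schema, call. = FALSE)
  df <- utils::read.csv(csv_file)
  for (nm in c(grep("^cv_", names(df), value = TRUE), "erp"))
    df[[nm]] <- as.numeric(df[[nm]])  # all-NA columns parse as logical
  if (nrow(df) != meta$n_rows)
    stop("database truncated: expected ", meta$n_rows, " rows, found ",
         nrow(df), call. = FALSE)
  structure(df, s2 = meta$s2, grid = meta$grid, cable = meta$cable,
            protocol = meta$protocol, row_index = meta$row_index,
            schema = meta$schema,
            class = c("restitution_db", "data.frame"))
}

#' @export
print.restitution_db <- function(x, ...) {
  cat(sprintf("restitution database: %d rows x %d s2 steps (%d feasible)\n",
              nrow(x), length(attr(x, "s2")), sum(x$ok)))
  invisible(x)
}

# internal: CV matrix view of a database
db_cv_matrix <- function(db) {
  k <- length(attr(db, "s2"))
  as.matrix(as.data.frame(db)[, paste0("cv_", seq_len(k))])
}
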