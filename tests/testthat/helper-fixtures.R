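# Shared fixtures. Expensive objects (the subsampled restitution database,
# reference restitution curve) are built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

# mid-range physiological marker set used throughout
ref_markers <- function() {
  cell_markers(cv_max = 80, apd_max = 180, h_min = 0.3,
               tau_in = 0.28, tau_open = 105)
}

ref_model <- function() invert_markers(ref_markers())

# subsampled database over a cv_max x apd_max slice of the published grid
fix_db <- function() {
  if (is.null(.fixtures$db)) {
    spec <- marker_grid(cv_max = seq(40, 140, 10), tau_in = 0.28,
                        h_min = 0.3, tau_open = 105,
                        apd_max = seq(150, 270, 15))
    .fixtures$db <- build_database(spec, cable_config(preset = "desk"),
                                   pacing_protocol())
  }
  .fixtures$db
}

# database rows usable as synthetic measurements (capture at >= 3 rungs)
fix_db_usable_rows <- function() {
  db <- fix_db()
  k <- length(attr(db, "s2"))
  cvm <- as.matrix(as.data.frame(db)[, paste0("cv_", seq_len(k))])
  unname(which(db$ok & rowSums(is.finite(cvm)) >= 3))
}

# CV values of a restitution on rungs where the local coupling interval
# still tracks s2: capturing rungs more than two ladder steps above the
# ERP. Just above the ERP the premature wave leaves the stimulus with a
# long latency, so downstream tissue sees a longer interval than s2 and
# the measured CV can rebound — monotonicity is only expected away from
# that boundary.
restitution_plateau_arm <- function(rc) {
  fin <- which(is.finite(rc$cv))
  if (is.finite(rc$erp)) {
    erp_idx <- which(abs(rc$s2 - rc$erp) < 1e-6)[1]
    if (!is.na(erp_idx)) fin <- fin[fin <= erp_idx - 3]
  }
  rc$cv[fin]
}

# one measurement synthesised from a database row (+ optional CV noise)
db_row_measurement <- function(db, r, noise_sd = 0, electrode = 1) {
  ladder <- attr(db, "s2")
  cv <- as.numeric(as.data.frame(db)[r, paste0("cv_", seq_along(ladder))])
  ok <- is.finite(cv)
  if (noise_sd > 0) cv[ok] <- cv[ok] + stats::rnorm(sum(ok), 0, noise_sd)
  structure(list(electrode = electrode, s2 = ladder, cv = cv,
                 erp = db$erp[r]),
            class = "cv_measurement")
}

# reference restitution curve at the desk preset
fix_restitution <- function() {
  if (is.null(.fixtures$rc)) {
    inv <- ref_model()
    .fixtures$rc <- restitution_curve(inv$params, inv$D,
                                      cable_config(preset = "desk"))
  }
  .fixtures$rc
}

# uniform surface model of the reference tissue
uniform_sheet_model <- function(size_cm, edge_mm) {
  inv <- ref_model()
  mesh <- sheet_mesh(size_cm, edge_mm)
  nv <- nrow(mesh$vertices)
  vp <- data.frame(tau_in = rep(inv$params$tau_in, nv),
                   tau_out = inv$params$tau_out,
                   tau_open = inv$params$tau_open,
                   tau_close = inv$params$tau_close)
  surface_model(mesh, vp, element_D = rep(inv$D, nrow(mesh$triangles)))
}

# random in-grid marker tuples (invertible ones) from the published ranges
random_grid_markers <- function(n, seed) {
  set.seed(seed)
  g <- enumerate_grid(marker_grid())
  out <- list()
  while (length(out) < n) {
    r <- sample.int(nrow(g), 1)
    m <- try(do.call(cell_markers, as.list(g[r, ])), silent = TRUE)
    if (inherits(m, "try-error")) next
    if (inherits(try(invert_markers(m), silent = TRUE), "try-error")) next
    out[[length(out) + 1]] <- m
  }
  out
}
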