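# small, fast case used by the recording tests: one catheter placement on a
# 5 x 5 cm sheet, single drive beat; the catheter sits clear of the pacing
# disk so every bipole records a travelling wave
small_case <- function(seed = 5, ...) {
  make_sheet_case(size_cm = 5, n_regions = 1, edge_mm = 2,
                  protocol = pacing_protocol(n_s1 = 1), seed = seed,
                  cv_pool = 80, apd_pool = 180,
                  snapshot_centres = rbind(c(30, 25)), ...)
}

test_that("cases are byte-identical under a fixed seed and in-grid by construction", {
  c1 <- make_sheet_case(size_cm = 4, n_regions = 3, edge_mm = 2, seed = 42,
                        snapshot_centres = rbind(c(20, 20)))
  c2 <- make_sheet_case(size_cm = 4, n_regions = 3, edge_mm = 2, seed = 42,
                        snapshot_centres = rbind(c(20, 20)))
  expect_identical(c1$region_markers, c2$region_markers)
  expect_identical(c1$region, c2$region)
  expect_identical(c1$model$element_D, c2$model$element_D)
  # sampled markers stay inside the published axis ranges
  g <- marker_grid()
  expect_true(all(c1$region_markers$cv_max %in% g$cv_max))
  expect_true(all(c1$region_markers$apd_max %in% g$apd_max))
  # a different seed gives a different draw somewhere
  c3 <- make_sheet_case(size_cm = 4, n_regions = 3, edge_mm = 2, seed = 43,
                        snapshot_centres = rbind(c(20, 20)))
  expect_false(identical(c1$region_markers, c3$region_markers) &&
               identical(c1$region, c3$region))
})

test_that("a single-region case is homogeneous", {
  case <- small_case()
  expect_equal(nrow(unique(case$model$vertex_params)), 1)
  expect_equal(length(unique(case$model$element_D)), 1)
})

test_that("the five-spline catheter geometry is correct", {
  mesh <- sheet_mesh(8, 2)
  snap <- place_pentaray(c(40, 40), 0, mesh)
  expect_equal(nrow(snap$poles), 20)
  expect_equal(nrow(snap$bipole_pos), 10)          # 5 splines x 2 bipoles
  expect_true(all(abs(snap$poles[, 3]) < 1e-12))   # coplanar on a flat sheet
  # electrode spacing along a spline is 4 mm
  r <- sqrt(rowSums(sweep(snap$poles[1:4, ], 2, c(40, 40, 0))^2))
  expect_equal(diff(r), rep(4, 3))
  # rotating by 72 degrees maps the pole set onto itself (spline relabelling)
  rot <- place_pentaray(c(40, 40), 72, mesh)
  key <- function(p) sort(apply(round(p, 6), 1, paste, collapse = ","))
  expect_equal(key(rot$poles), key(snap$poles))
  # a footprint hanging off the sheet is refused
  expect_error(place_pentaray(c(2, 2), 0, mesh), "leaves the mesh")
})

test_that("noiseless virtual recordings agree with threshold-crossing LATs", {
  case <- small_case()
  rec <- record_case(case, "A", s2_values = 343,
                     cfg = sim_config(preset = "desk"))
  expect_true(all(rec$captured[, 1]))
  run <- simulate_pacing(case$model, rec$stim, case$protocol, s2 = 343,
                         cfg = sim_config(preset = "desk"))
  ref <- sample_at_electrodes(run, rec$positions, case$model$mesh)
  # the two annotation conventions (first electrogram extremum vs upward
  # threshold crossing) differ by a constant lag of a few ms; after that
  # offset they agree electrode-by-electrode
  d <- rec$lat[, 1] - ref
  expect_lt(max(abs(d - mean(d))), 2 + max(diff(run$time)))
})

test_that("a premature beat below the regional ERP is flagged non-captured", {
  case <- small_case()
  rc <- fix_restitution()                 # same tissue as the case regions
  rec <- record_case(case, "A", s2_values = rc$erp - 35,
                     cfg = sim_config(preset = "desk"))
  expect_false(any(rec$captured))
  expect_true(all(is.na(rec$lat)))
})

test_that("total dropout erases every recording", {
  case <- small_case(lat_jitter_sd_ms = 0, dropout_prob = 1)
  rec <- record_case(case, "A", s2_values = 343,
                     cfg = sim_config(preset = "desk"))
  expect_true(all(is.na(rec$lat)))
  expect_false(any(rec$captured))
})

test_that("LAT jitter is reproducible under the case seed", {
  r1 <- record_case(small_case(lat_jitter_sd_ms = 2), "A", s2_values = 343,
                    cfg = sim_config(preset = "desk"))
  r2 <- record_case(small_case(lat_jitter_sd_ms = 2), "A", s2_values = 343,
                    cfg = sim_config(preset = "desk"))
  expect_identical(r1$lat, r2$lat)
})

test_that("processing recordings yields one measurement per bipole", {
  case <- small_case()
  rec <- record_case(case, "A", s2_values = c(343, 329.42),
                     cfg = sim_config(preset = "desk"))
  proc <- process_recordings(rec)
  expect_length(proc$measurements, nrow(rec$positions))
  m <- proc$measurements[[1]]
  expect_s3_class(m, "cv_measurement")
  expect_equal(m$s2, rec$s2)
  expect_true(all(is.na(m$cv) | m$cv <= 200))
})
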