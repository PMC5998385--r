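test_that("P1 operators satisfy the FEM identities", {
  mod <- uniform_sheet_model(c(2, 2), 1)
  ops <- assemble_fem(mod)
  expect_lt(max(abs(Matrix::rowSums(ops$K))), 1e-12)   # constants in null space
  expect_equal(sum(ops$mass), sum(mesh_areas(mod$mesh)), tolerance = 1e-12)
  expect_true(all(ops$mass > 0))
})

test_that("degenerate triangles are reported by element id", {
  v <- rbind(c(0, 0, 0), c(10, 0, 0), c(0, 10, 0), c(10, 0, 0))
  tr <- rbind(c(1, 2, 3), c(2, 4, 1))  # second triangle has zero area
  mod <- surface_model(tri_mesh(v, tr),
                       data.frame(tau_in = rep(0.28, 4), tau_out = 4.6,
                                  tau_open = 105, tau_close = 150),
                       element_D = c(0.01, 0.01))
  expect_error(assemble_fem(mod), "degenerate.*2")
})

test_that("an unstimulated sheet stays at rest", {
  mod <- uniform_sheet_model(c(2, 2), 2)
  run <- simulate_pacing(mod, stimulus_spec(c(10, 10, 0), amplitude = 0),
                         pacing_protocol(n_s1 = 1), s2 = NULL,
                         cfg = sim_config(preset = "desk", t_end_ms = 50),
                         record_positions = rbind(c(10, 10, 0)))
  expect_true(all(abs(run$traces) < 1e-12))
  expect_true(all(is.na(run$lat)))
})

test_that("plane-wave CV on a uniform sheet matches the 1D cable within 5%", {
  mod <- uniform_sheet_model(c(6, 1.5), 0.5)
  strip <- which(mod$mesh$vertices[, 1] <= 1)
  run <- simulate_pacing(mod, stimulus_spec(c(0, 7.5, 0)),
                         pacing_protocol(), s2 = 343,
                         cfg = sim_config(preset = "desk"),
                         stim_vertices = strip)
  l <- sample_at_electrodes(run, rbind(c(20, 7.5, 0), c(50, 7.5, 0)),
                            mod$mesh)
  cv2d <- 30 / diff(l) * 100
  inv <- ref_model()
  rc <- run_cable(inv$params, inv$D,
                  cable_config(dx_um = 500, dt_ode_us = 20, dt_pde_us = 200),
                  pacing_protocol(), s2 = 343)
  lat <- vapply(c(1, 4), function(j) {
    i <- which(rc$time > rc$s2_time + 2 & rc$vm[, j] >= 0.1)[1]
    rc$time[i]
  }, numeric(1))
  cv1d <- 0.9 / diff(lat) * 1000
  expect_lt(abs(cv2d - cv1d) / cv1d, 0.05)
  # LAT increases monotonically along the propagation direction
  lats <- sample_at_electrodes(run, cbind(seq(10, 55, 5), 7.5, 0), mod$mesh)
  expect_true(all(diff(lats) > 0))
  # isochrones start at the stimulus: earliest activation inside the strip
  expect_equal(which.min(run$lat) %in% strip, TRUE)
})

test_that("a premature beat below the tissue ERP dies out near the stimulus", {
  rc <- fix_restitution()
  mod <- uniform_sheet_model(c(6, 1.5), 1)
  run <- simulate_pacing(mod, stimulus_spec(c(0, 7.5, 0)),
                         pacing_protocol(), s2 = rc$erp - 35,
                         cfg = sim_config(preset = "desk"))
  # the big stimulus disk launches a decremental wavelet into barely
  # recovered tissue; it must extinguish within a couple of centimetres
  # and never reach the body of the sheet
  x <- mod$mesh$vertices[, 1]
  expect_true(all(is.na(run$lat[x > 25])))
})

test_that("a high-ERP patch between stimulus and distal tissue causes functional block", {
  inv_norm <- ref_model()
  # markers with a cable ERP above 300 ms (long APD, slow late repolarisation)
  inv_long <- invert_markers(cell_markers(cv_max = 80, apd_max = 240,
                                          h_min = 0.07, tau_in = 0.31,
                                          tau_open = 75))
  mesh <- sheet_mesh(c(8, 1.5), 1)
  nv <- nrow(mesh$vertices)
  x <- mesh$vertices[, 1]
  patch <- x >= 30 & x <= 50
  vp <- data.frame(
    tau_in = rep(inv_norm$params$tau_in, nv),
    tau_out = ifelse(patch, inv_long$params$tau_out, inv_norm$params$tau_out),
    tau_open = ifelse(patch, inv_long$params$tau_open, inv_norm$params$tau_open),
    tau_close = ifelse(patch, inv_long$params$tau_close, inv_norm$params$tau_close))
  xc <- mesh_centroids(mesh)[, 1]
  eD <- ifelse(xc >= 30 & xc <= 50, inv_long$D, inv_norm$D)
  mod <- surface_model(mesh, vp, element_D = eD)
  # coupling above the background ERP but inside the patch's refractory
  # window: without the patch the premature wave crosses the whole strip
  ctrl_vp <- vp; ctrl_vp[] <- lapply(names(vp), function(nm)
    rep(unclass(inv_norm$params)[[nm]], nv))
  ctrl <- surface_model(mesh, ctrl_vp,
                        element_D = rep(inv_norm$D, length(eD)))
  s2 <- 269.2
  run_ctrl <- simulate_pacing(ctrl, stimulus_spec(c(0, 7.5, 0)),
                              pacing_protocol(), s2 = s2,
                              cfg = sim_config(preset = "desk"))
  run <- simulate_pacing(mod, stimulus_spec(c(0, 7.5, 0)),
                         pacing_protocol(), s2 = s2,
                         cfg = sim_config(preset = "desk"))
  proximal <- which(x < 25)
  distal <- which(x > 55)
  expect_true(all(is.finite(run_ctrl$lat[distal])))  # control conducts
  expect_true(all(is.finite(run$lat[proximal])))     # captured pre-patch
  expect_true(all(is.na(run$lat[distal])))           # functional block
})

test_that("electrode sampling takes the nearest vertex and propagates block", {
  mod <- uniform_sheet_model(c(2, 2), 2)
  lat <- seq_len(nrow(mod$mesh$vertices)) * 1.0
  lat[5] <- NA
  lm <- structure(list(lat = lat), class = "lat_map")
  v7 <- mod$mesh$vertices[7, ]
  expect_equal(sample_at_electrodes(lm, rbind(v7), mod$mesh), 7)
  expect_equal(sample_at_electrodes(lm, rbind(v7 + 0.4), mod$mesh), 7)
  v5 <- mod$mesh$vertices[5, ]
  expect_true(is.na(sample_at_electrodes(lm, rbind(v5), mod$mesh)))
  # coincident electrodes sample identically
  s <- sample_at_electrodes(lm, rbind(v7, v7), mod$mesh)
  expect_equal(s[1], s[2])
})

test_that("configuration guards reject inconsistent steps and missing disks", {
  expect_error(sim_config(dt_ode_us = 30, dt_pde_us = 100), "multiple")
  mod <- uniform_sheet_model(c(2, 2), 2)
  expect_error(simulate_pacing(mod, stimulus_spec(c(500, 500, 0)),
                               pacing_protocol(n_s1 = 1), s2 = NULL,
                               cfg = sim_config(t_end_ms = 10)),
               "does not intersect")
  expect_error(stimulus_spec(c(0, 0, 0), radius_cm = -1), "radius")
})
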