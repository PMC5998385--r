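test_that("ionic current vanishes at rest, repolarises at plateau, and is inward-blocking below threshold", {
  p <- mms_params(tau_in = 0.3, tau_out = 6, tau_open = 120, tau_close = 150)
  expect_identical(ionic_current(0, 1, p), 0)
  expect_equal(ionic_current(1, 0.4, p), -1 / p$tau_out)
  expect_equal(ionic_current(1, 1, p), -1 / p$tau_out)
  # below the gate threshold the total rate is strictly negative
  expect_lt(ionic_current(0.05, 1, p), 0)
  # and an unstimulated sub-threshold perturbation decays back to rest
  tr <- integrate_cell(p, vm0 = 0.05, h0 = 1, dt = 0.01, t_end = 200)
  expect_lt(abs(tr$vm[length(tr$vm)]), 1e-6)
  expect_true(all(diff(tr$vm) <= 1e-12))
})

test_that("gate dynamics recover below threshold and close above it", {
  p <- mms_params(tau_in = 0.3, tau_out = 6, tau_open = 100, tau_close = 150)
  expect_identical(gate_rate(0, 1, p), 0)
  expect_identical(gate_rate(1, 0, p), 0)
  expect_equal(gate_rate(0, 0.5, p), 0.005)
  expect_equal(gate_rate(0.5, 0.5, p), -0.5 / 150)
})

test_that("no-pacemaker property holds for random parameter sets and sub-threshold states", {
  mks <- random_grid_markers(100, seed = 202)
  vm0 <- c(0.02, 0.05, 0.09)
  h0 <- c(0.1, 0.6, 1)
  init <- expand.grid(vm = vm0, h = h0)
  for (m in mks) {
    inv <- invert_markers(m)
    p <- inv$params
    vm <- init$vm; h <- init$h
    dt <- 0.02
    hmin_seen <- min(h); hmax_seen <- max(h)
    for (k in seq_len(10000)) {  # 200 ms
      dv <- ionic_current(vm, h, p)
      dh <- gate_rate(vm, h, p)
      vm <- vm + dt * dv
      h <- h + dt * dh
      hmin_seen <- min(hmin_seen, h); hmax_seen <- max(hmax_seen, h)
    }
    expect_true(all(abs(vm) < 1e-4))
    # gate bounded under forward Euler at the documented step-size bound
    expect_gte(hmin_seen, 0)
    expect_lte(hmax_seen, 1)
  }
})

test_that("leading-order h_min matches arithmetic and the numerical null-cline minimum", {
  p <- mms_params(tau_in = 0.3, tau_out = 6, tau_open = 120, tau_close = 150)
  m <- leading_order_markers(p, D = 0.001)
  expect_equal(m$h_min, 1.2 / 4.86, tolerance = 1e-9)
  # oracle: numerically locate the minimum of the null-cline
  # h(v) = tau_in / (tau_out (v - v_gate)(1 - v)) over (v_gate, 1)
  v <- seq(p$v_gate + 1e-4, 1 - 1e-4, length.out = 20001)
  h_null <- p$tau_in / (p$tau_out * (v - p$v_gate) * (1 - v))
  expect_equal(m$h_min, min(h_null), tolerance = 1e-6)
})

test_that("APDmax equals tau_close when h_min is 1/e", {
  tau_in <- 0.2; v_gate <- 0.1
  tau_out <- 4 * tau_in / (exp(-1) * (1 - v_gate)^2)  # forces h_min = 1/e
  p <- mms_params(tau_in, tau_out, tau_open = 100, tau_close = 150,
                  v_gate = v_gate)
  m <- leading_order_markers(p, D = 0.001)
  expect_equal(m$h_min, exp(-1), tolerance = 1e-12)
  expect_equal(m$apd_max, 150, tolerance = 1e-9)
})

test_that("marker inversion matches hand arithmetic", {
  inv <- invert_markers(cell_markers(cv_max = 60, apd_max = 150,
                                     h_min = 0.25, tau_in = 0.3,
                                     tau_open = 100))
  expect_equal(inv$params$tau_out, 4 * 0.3 / (0.25 * 0.81), tolerance = 1e-9)
  inv2 <- invert_markers(cell_markers(cv_max = 60, apd_max = 120,
                                      h_min = 0.5, tau_in = 0.3,
                                      tau_open = 100))
  expect_equal(inv2$params$tau_close, 120 / log(2), tolerance = 1e-9)
})

test_that("marker inversion is an exact bijection on the valid grid domain", {
  for (m in random_grid_markers(50, seed = 303)) {
    inv <- invert_markers(m)
    back <- leading_order_markers(inv$params, inv$D)
    for (f in c("cv_max", "apd_max", "h_min", "tau_in", "tau_open"))
      expect_equal(back[[f]], m[[f]], tolerance = 1e-9)
  }
})

test_that("invalid parameters and markers are rejected", {
  expect_error(mms_params(-1, 6, 100, 150), "time constants")
  expect_error(mms_params(0.3, 6, 100, 150, v_gate = 0.7), "v_gate")
  expect_error(mms_params(6, 0.3, 100, 150), "tau_in")
  expect_error(cell_markers(60, 150, 1.2, 0.3, 100), "h_min")
  expect_error(leading_order_markers(
    mms_params(0.3, 6, 100, 150), D = -1), "D must be")
  # tau_out too small for a repolarised wave
  expect_error(leading_order_markers(
    structure(list(tau_in = 1, tau_out = 1.1, tau_open = 100,
                   tau_close = 150, v_gate = 0.1), class = "mms_params"),
    D = 0.001), "h_min >= 1")
})

test_that("parameter sets round-trip through JSON with unit-suffixed fields", {
  p <- mms_params(0.28, 4.6, 105, 149.5)
  f <- withr::local_tempfile(fileext = ".json")
  mms_params_to_json(p, f)
  q <- mms_params_from_json(f)
  expect_equal(unclass(q), unclass(p), tolerance = 1e-12)
  expect_match(readLines(f), "tau_in_ms")
})
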