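test_that("Delaunay triangulation satisfies the empty-circumcircle property", {
  for (seed in 1:4) {
    set.seed(seed)
    pts <- cbind(stats::runif(15), stats::runif(15))
    tri <- delaunay2d(pts)
    expect_true(nrow(tri) >= 1)
    for (k in seq_len(nrow(tri))) {
      cc <- atriafit:::circumcircle2d(pts[tri[k, 1], ], pts[tri[k, 2], ],
                                      pts[tri[k, 3], ])
      d2 <- (pts[, 1] - cc[1])^2 + (pts[, 2] - cc[2])^2
      inside <- d2 < cc[3] * (1 - 1e-9)
      inside[tri[k, ]] <- FALSE
      expect_false(any(inside))
    }
  }
  # a unit square triangulates into two triangles of total area 1
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  tri <- delaunay2d(sq)
  area <- sum(apply(tri, 1, function(v) {
    a <- sq[v[2], ] - sq[v[1], ]; b <- sq[v[3], ] - sq[v[1], ]
    abs(a[1] * b[2] - a[2] * b[1]) / 2
  }))
  expect_equal(area, 1, tolerance = 1e-12)
  expect_error(delaunay2d(cbind(1:5, 2 * (1:5))), "degenerate|collinear")
})

test_that("LAT detection returns the first qualifying extremum", {
  t <- seq(100, 140, by = 0.5)
  # analytic biphasic wavelet: extrema at 120 +/- 2, peak first at 118
  w <- -(t - 120) * exp(-(t - 120)^2 / (2 * 4))
  tr <- data.frame(time_ms = t, value = w)
  expect_equal(detect_lat(tr, threshold = 0.1), 118)
  # flipping the sign puts the valley first; it is still the first extremum
  tr2 <- data.frame(time_ms = t, value = -w)
  expect_equal(detect_lat(tr2, threshold = 0.1), 118)
  # polarity filter skips to the first extremum of the requested sign
  expect_equal(detect_lat(tr, threshold = 0.1, polarity = "negative"), 122)
  # zero trace: nothing to detect
  expect_true(is.na(detect_lat(data.frame(time_ms = t, value = 0 * t))))
  # sub-threshold deflections do not count
  expect_true(is.na(detect_lat(tr, threshold = 10)))
  expect_error(detect_lat(tr, window = c(130, 120)), "empty")
  expect_error(detect_lat(tr, window = c(500, 600)), "outside")
})

test_that("EGM conditioning turns a slow hump into a negligible deflection", {
  t <- seq(0, 100, by = 0.2)
  fast <- exp(-(t - 30)^2 / 2)        # ~2 ms deflection (depolarisation)
  slow <- exp(-(t - 70)^2 / 200)      # ~20 ms hump (repolarisation)
  cond <- condition_egm(data.frame(time_ms = t, value = fast + slow))
  fast_amp <- max(abs(cond$value[t < 50]))
  slow_amp <- max(abs(cond$value[t > 50]))
  expect_gt(fast_amp / slow_amp, 5)
})

test_that("the CV estimator is exact on affine LAT fields in any plane", {
  for (seed in 1:3) {
    set.seed(seed)
    # random planar patch embedded in 3D
    u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
    w <- stats::rnorm(3); w <- w - sum(w * u) * u; w <- w / sqrt(sum(w^2))
    uv <- cbind(stats::runif(10, 0, 30), stats::runif(10, 0, 30))
    pos <- uv %*% rbind(u, w) + matrix(stats::rnorm(3), 10, 3, byrow = TRUE)
    v <- stats::runif(1, 0.3, 1.5)            # mm/ms
    lats <- uv[, 1] / v                        # planar wave along u
    cv <- local_cv_field(pos, lats)
    expect_equal(cv, rep(v * 100, 10), tolerance = 1e-6)
  }
})

test_that("constant LATs yield no finite CV (zero gradient everywhere)", {
  set.seed(2)
  pos <- cbind(stats::runif(8, 0, 20), stats::runif(8, 0, 20), 0)
  expect_true(all(is.na(local_cv_field(pos, rep(42, 8)))))
})

test_that("median pooling bounds the influence of one corrupted electrode", {
  snap <- place_pentaray(c(40, 40), 0, sheet_mesh(8, 2))
  pos <- snap$bipole_pos
  v <- 0.7
  lats <- pos[, 1] / v
  clean <- local_cv_field(pos, lats)
  bad <- lats; bad[4] <- bad[4] + 50
  corrupted <- local_cv_field(pos, bad)
  others <- setdiff(seq_along(lats), 4)
  rel <- abs(corrupted[others] - clean[others]) / clean[others]
  expect_true(all(rel < 0.15))
})

test_that("the physiological cut-off removes only supra-physiological values", {
  expect_equal(filter_physiological(c(50, 150, 250)), c(50, 150, NA))
  expect_equal(filter_physiological(c(10, 200)), c(10, 200))
  # the cut-off derivation rule (mean + 2 SD, rounded) on a stated population
  expect_equal(round(88 + 2 * 35, -1), 160)
})

test_that("ERP estimation follows the largest non-capturing interval", {
  s2 <- c(343, 310, 280, 248, 224, 203)
  expect_equal(estimate_erp(s2, c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)), 248)
  expect_true(is.na(estimate_erp(s2, rep(TRUE, 6))))
  expect_warning(
    erp <- estimate_erp(s2, c(TRUE, FALSE, TRUE, FALSE, FALSE, FALSE)),
    "non-monotone")
  expect_equal(erp, 310)
})

test_that("electrode tables round-trip through CSV", {
  df <- data.frame(electrode_id = 1:2, x_mm = c(0, 1), y_mm = 0, z_mm = 0,
                   s2_ms = 343, lat_ms = c(10.5, NA), captured = c(TRUE, FALSE))
  f <- withr::local_tempfile(fileext = ".csv")
  write_electrode_csv(df, f)
  back <- read_electrode_csv(f)
  expect_equal(back$lat_ms, df$lat_ms)
  expect_equal(back$captured, df$captured)
  expect_error(read_electrode_csv(
    withr::local_tempfile(lines = "a,b\n1,2", fileext = ".csv")),
    "missing columns")
})
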