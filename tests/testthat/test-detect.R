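test_that("saturation matches hand-computed HSV values", {
  px <- function(r, g, b) array(c(r, g, b), dim = c(1, 1, 3))
  expect_equal(saturation_image(px(0.8, 0.4, 0.4))[1, 1], 0.5)
  expect_equal(saturation_image(px(1, 1, 1))[1, 1], 0)
  expect_equal(saturation_image(px(0, 0, 0))[1, 1], 0)
  expect_equal(saturation_image(px(0, 0.5, 0))[1, 1], 1)
  # invariance to uniform brightness scaling
  img <- array(runif(10 * 8 * 3, 0.1, 1), dim = c(10, 8, 3))
  expect_equal(saturation_image(img * 0.6), saturation_image(img),
               tolerance = 1e-12)
})

test_that("Otsu threshold agrees with a brute-force oracle", {
  set.seed(404)
  for (rep in 1:8) {
    g <- c(rnorm(60, 0.25, 0.05), rnorm(40, 0.75, 0.08))
    g <- pmin(pmax(g, 0), 1)
    expect_equal(otsu_threshold(g), otsu_brute_force(g))
  }
  # clean bimodal: threshold separates the two modes
  thr <- otsu_threshold(c(rep(0.2, 50), rep(0.8, 50)))
  expect_gt(thr, 0.2)
  expect_lt(thr, 0.8)
  expect_true(is.na(otsu_threshold(rep(0.4, 100))))
})

test_that("Otsu threshold is variance-equivalent to the EBImage reference", {
  # tie-breaking differs (EBImage reports the plateau midpoint, we the
  # first maximizer), so compare the attained between-class variance
  between_var <- function(v, thr) {
    lo <- v <= thr
    if (!any(lo) || all(lo)) return(-Inf)
    mean(lo) * mean(!lo) * (mean(v[lo]) - mean(v[!lo]))^2
  }
  set.seed(405)
  for (rep in 1:4) {
    g <- matrix(pmin(pmax(c(rnorm(120, 0.3, 0.07),
                            rnorm(80, 0.7, 0.06)), 0), 1), 20, 10)
    ref <- EBImage::otsu(EBImage::Image(g), range = c(0, 1), levels = 256)
    ours <- otsu_threshold(g)
    expect_equal(between_var(as.numeric(g), ours),
                 between_var(as.numeric(g), ref), tolerance = 1e-6)
    # both cleanly separate the two modes
    expect_gt(ours, 0.4); expect_lt(ours, 0.6)
    expect_gt(ref, 0.4); expect_lt(ref, 0.6)
  }
})

test_that("binarize splits bimodal data and signals constant rasters", {
  g <- matrix(c(rep(0.2, 30), rep(0.9, 30)), 6, 10)
  b <- binarize(g)
  expect_identical(sort(unique(as.numeric(b))), c(0, 1))
  expect_identical(b, binarize(g, detection_config()))
  expect_equal(as.numeric(b), as.numeric(g > attr(b, "threshold")))
  bf <- binarize(g, detection_config(threshold_method = "fixed",
                                     fixed_threshold = 0.5))
  expect_equal(as.numeric(bf), as.numeric(g > 0.5))
  const <- binarize(matrix(0.4, 5, 5))
  expect_true(all(is.na(const)))
  expect_true(isTRUE(attr(const, "no_interface")))
})

test_that("row profile averages rows and smooths with a truncated window", {
  b <- rbind(matrix(1, 4, 6), matrix(0, 4, 6))
  roi <- vial_roi(1, 6, 1, 8, 1)
  raw <- row_profile(b, roi, detection_config(smooth_window_rows = 1))
  expect_equal(raw, c(1, 1, 1, 1, 0, 0, 0, 0))
  sm <- row_profile(b, roi, detection_config(smooth_window_rows = 3))
  # truncated means at the edges, 2/3 and 1/3 at the step
  expect_equal(sm, c(1, 1, 1, 2 / 3, 1 / 3, 0, 0, 0))
  expect_error(row_profile(b, vial_roi(1, 7, 1, 8, 1)), "ROI exceeds")
})

test_that("interface localization interpolates the half crossing", {
  cfg <- detection_config(smooth_window_rows = 1)
  roi <- vial_roi(1, 10, 1, 12, 1)
  # step 1 -> 0 between rows 6 and 7: crossing at the shared edge, 6.5
  p <- c(rep(1, 6), rep(0, 6))
  det <- detect_interface(p, roi, cfg)
  expect_equal(det$row, 6.5)
  expect_identical(det$flag, "ok")
  expect_identical(det$n_crossings, 1L)
  # 0.8 -> 0.2: linear interpolation, crossing halfway again
  p2 <- c(rep(0.8, 6), rep(0.2, 6))
  expect_equal(detect_interface(p2, roi, cfg)$row, 6.5)
  # asymmetric bracketing: 0.9 -> 0.3 crosses 0.5 at 2/3 of the gap
  p3 <- c(rep(0.9, 6), rep(0.3, 6))
  expect_equal(detect_interface(p3, roi, cfg)$row, 6 + 2 / 3)
  # flat profile: no interface
  none <- detect_interface(rep(0.9, 12), roi, cfg)
  expect_true(is.na(none$row))
  expect_identical(none$flag, "no_interface")
  # crossing hugging the ROI bottom is flagged clamped
  deep <- detect_interface(c(rep(1, 10), rep(0, 2)), roi, cfg)
  expect_identical(deep$flag, "clamped")
})

test_that("gel-top offset shifts the reported frame row, not the depth", {
  cfg <- detection_config(smooth_window_rows = 1)
  p <- c(rep(1, 6), rep(0, 6))
  roi_lo <- vial_roi(1, 10, 1, 12, 1)
  roi_hi <- vial_roi(1, 10, 21, 32, 21)
  a <- detect_interface(p, roi_lo, cfg)
  b <- detect_interface(p, roi_hi, cfg)
  expect_equal(b$row - a$row, 20)
})

test_that("zero-noise frames localize the front to under half a pixel", {
  g <- vial_geometry()
  cfg <- render_config(noise_sd = 0)
  s <- render_series(seq(0, 1200, by = 300), 11.55e-9, g, config = cfg)
  tr <- track_series(s, list(gel_roi(g)))[[1]]
  ok <- tr$flags == "ok" & tr$times_s > 0
  err_px <- abs(tr$position_mm[ok] / g$mm_per_px -
                  s$truth_depth_mm[ok] / g$mm_per_px)
  expect_true(all(err_px < 0.5))
})

test_that("detection is invariant to uniform brightness scaling", {
  g <- vial_geometry()
  s <- render_series(c(0, 900), 6e-9, g,
                     config = render_config(noise_sd = 0, illum_gradient = 0))
  base <- detect_depth_mm(s$frames[[2]], g)
  for (sc in c(0.5, 0.75, 1)) {
    dim_img <- s$frames[[2]] * sc
    expect_equal(detect_depth_mm(dim_img, g), base, tolerance = 1e-9)
  }
})

test_that("replicate vials under noise disagree by less than two pixels", {
  g <- vial_geometry()
  mv <- render_multivial(rep(6e-9, 10), times_s = c(0, 600, 1200),
                         geometry = g, config = render_config(seed = 3L))
  trs <- track_series(mv)
  for (f in 2:3) {
    p <- vapply(trs, function(t) t$position_px[f], numeric(1))
    fl <- vapply(trs, function(t) t$flags[f], character(1))
    expect_true(all(fl == "ok"))
    expect_lt(stats::sd(p), 2)
  }
})

test_that("track_series sets the reference from the blank frame", {
  g <- vial_geometry()
  s <- render_series(c(0, 600), 6e-9, g, config = render_config(noise_sd = 0))
  tr <- track_series(s, list(gel_roi(g)))[[1]]
  # blank gel has no interface: reference falls back to the gel surface
  expect_identical(tr$flags[1], "no_interface")
  expect_equal(tr$x0_px, g$gel_top_row - 0.5)
  expect_true(is.na(tr$position_mm[1]))
  expect_gt(tr$position_mm[2], 0)
})
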