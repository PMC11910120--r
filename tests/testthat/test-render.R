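noise_free <- render_config(noise_sd = 0)

test_that("pure-phase columns render exactly the filtered indicator colours", {
  g <- vial_geometry()
  ind <- bromothymol_blue()
  cfg <- render_config(noise_sd = 0, illum_gradient = 0)
  gel <- g$gel_top_row:(g$gel_top_row + g$gel_rows - 1L)
  filt <- c(1, 1, 1 - cfg$yellow_filter_strength)

  img0 <- render_frame(0, g, ind, cfg)
  for (ch in 1:3)
    expect_true(all(abs(img0[gel, , ch] -
                          ind$base_color[ch] * filt[ch]) < 1e-12))
  imgF <- render_frame(g$gel_height_mm, g, ind, cfg)
  for (ch in 1:3)
    expect_true(all(abs(imgF[gel, , ch] -
                          ind$acid_color[ch] * filt[ch]) < 1e-12))
})

test_that("the logistic midpoint row shows the 50/50 colour mix", {
  g <- vial_geometry()
  ind <- bromothymol_blue()
  cfg <- render_config(noise_sd = 0, illum_gradient = 0,
                       yellow_filter_strength = 0)
  # put the front exactly at the centre of a gel row
  j <- 30L
  depth <- (j - 0.5) * g$mm_per_px
  img <- render_frame(depth, g, ind, cfg)
  mid <- 0.5 * ind$acid_color + 0.5 * ind$base_color
  expect_equal(as.numeric(img[g$gel_top_row + j - 1L, 1, ]), mid,
               tolerance = 1e-12)
})

test_that("yellow filter scales only the blue channel and is monotone", {
  img <- array(runif(30 * 20 * 3), dim = c(30, 20, 3))
  expect_identical(apply_yellow_filter(img, 0), img)
  blue <- array(0, dim = c(2, 2, 3)); blue[, , 3] <- 1
  out <- apply_yellow_filter(blue, 1)
  expect_true(all(out == 0))
  s <- seq(0, 1, by = 0.2)
  b <- vapply(s, function(si) apply_yellow_filter(img, si)[4, 7, 3],
              numeric(1))
  expect_true(all(diff(b) <= 0))
  r <- vapply(s, function(si) apply_yellow_filter(img, si)[4, 7, 1],
              numeric(1))
  expect_true(all(r == r[1]))
})

test_that("rendering is deterministic for a fixed seed", {
  cfg <- render_config(seed = 11L)
  a <- render_series(c(0, 300, 600), 5e-9, config = cfg)
  b <- render_series(c(0, 300, 600), 5e-9, config = cfg)
  expect_identical(a$frames, b$frames)
  cfg2 <- render_config(seed = 12L)
  c <- render_series(c(0, 300, 600), 5e-9, config = cfg2)
  expect_false(identical(a$frames[[2]], c$frames[[2]]))
})

test_that("series ground truth obeys the sqrt-t law exactly", {
  D <- 3.7e-9
  s <- render_series(seq(0, 1200, by = 300), D, config = noise_free)
  d_m <- s$truth_depth_mm / 1000
  slope <- sum(d_m^2 * s$times_s) / sum(s$times_s^2)   # d^2 = slope * t
  expect_equal(slope, 2 * D, tolerance = 1e-12)
})

test_that("fronts beyond the gel clamp and are flagged in the truth", {
  s <- render_series(seq(0, 3600, by = 300), 11.55e-9, config = noise_free)
  expect_true(any(s$clamped))
  expect_true(all(s$truth_depth_mm <= s$geometry$gel_height_mm))
  # clamp onset matches the analytic crossing time of the gel height
  t_exit <- (s$geometry$gel_height_mm / 1000)^2 / (2 * 11.55e-9)
  expect_identical(s$clamped, s$times_s > t_exit)
})

test_that("a series must start with the pre-gassing reference frame", {
  expect_error(render_series(c(300, 600), 1e-9), "start at 0")
})

test_that("multivial composites reproduce single-vial gel columns", {
  g <- vial_geometry()
  cfg <- render_config(noise_sd = 0)
  mv <- render_multivial(c(2e-9, 8e-9), times_s = c(0, 600),
                         geometry = g, config = cfg)
  expect_length(mv$rois, 2)
  for (v in 1:2) {
    cfg_v <- cfg
    cfg_v$seed <- (cfg$seed + 104729L * v) %% .Machine$integer.max
    single <- render_series(c(0, 600), c(2e-9, 8e-9)[v], g, config = cfg_v)
    roi <- mv$rois[[v]]
    crop <- mv$frames[[2]][roi$row_start:roi$row_end,
                           roi$col_start:roi$col_end, ]
    ref <- single$frames[[2]][roi$row_start:roi$row_end, 1:g$width_px, ]
    expect_equal(crop, ref, tolerance = 1e-14)
  }
})

test_that("multivial refuses more than ten vials", {
  expect_error(render_multivial(rep(1e-9, 11)), "10")
})
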