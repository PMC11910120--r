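test_that("velocity and pseudo diffusion reproduce hand calculations", {
  expect_equal(interface_velocity(0, 6.448e-3, 1800), 3.582222e-6,
               tolerance = 1e-6)
  expect_equal(pseudo_diffusion(0, 6.448e-3, 1800), 11.55e-9,
               tolerance = 1e-3)
  # direction-free displacement
  expect_equal(pseudo_diffusion(2e-3, 5e-3, 600),
               pseudo_diffusion(5e-3, 2e-3, 600))
  expect_error(interface_velocity(0, 1e-3, 0), "t must")
  expect_error(pseudo_diffusion(0, 1e-3, -5), "t must")
})

test_that("porosity is the gravimetric void fraction", {
  expect_equal(porosity(1.000, 0.042), 0.958)
  expect_equal(porosity(2, 2), 0)
  expect_error(porosity(1, 1.2), "exceed")
  expect_error(porosity(0, 0.1), "> 0")
})

test_that("fold ratio of the two reported hydrogels is about 34", {
  a <- summarize_replicates(fit_front(exact_track(11.55e-9)), "agarose")
  b <- summarize_replicates(fit_front(exact_track(0.34e-9)), "silica")
  expect_equal(fold_ratio(a, b), 11.55 / 0.34, tolerance = 1e-9)
  expect_equal(fold_ratio(a, b), 33.97, tolerance = 1e-3)
})

test_that("an exact sqrt-t track yields a constant per-time coefficient", {
  D <- 4.2e-9
  fit <- fit_front(exact_track(D))
  expect_s3_class(fit, "front_fit")
  expect_true(all(abs(fit$per_time$d_pseudo_m2_s - D) < 1e-22))
  expect_equal(fit$replicate_mean_D, D, tolerance = 1e-12)
  expect_equal(fit$fitted_D, D, tolerance = 1e-12)
  expect_equal(unname(coef(fit)), c(D, D), tolerance = 1e-12)
  expect_true(all(abs(residuals(fit)) < 1e-15))
})

test_that("flagged and pre-gassing points are excluded from the fit", {
  tr <- exact_track(3e-9, times = seq(300, 1500, by = 300))
  full <- fit_front(tr)
  tr$flags[6] <- "clamped"           # last point
  tr$position_mm[6] <- 0             # corrupt it: must not matter
  part <- fit_front(tr)
  expect_equal(part$n_used, 4L)
  expect_equal(part$fitted_D, full$fitted_D, tolerance = 1e-12)
  tr$flags[] <- "no_interface"
  tr$flags[2] <- "ok"
  expect_error(fit_front(tr), "usable points")
})

test_that("the fit is invariant to the ordering of the points", {
  set.seed(11)
  tr <- exact_track(5e-9, times = seq(300, 1800, by = 300))
  tr$position_mm <- tr$position_mm + c(0, rnorm(6, 0, 0.05))
  perm <- c(1, sample(2:7))
  tr2 <- list(vial_id = 1, times_s = tr$times_s[perm],
              position_mm = tr$position_mm[perm], flags = tr$flags[perm])
  expect_equal(fit_front(tr2)$fitted_D, fit_front(tr)$fitted_D,
               tolerance = 1e-15)
  expect_equal(fit_front(tr2)$replicate_mean_D, fit_front(tr)$replicate_mean_D,
               tolerance = 1e-15)
})

test_that("a decelerating front shows a non-increasing per-time coefficient", {
  # sub-diffusive track: d ~ t^0.4, so d^2 / (2t) must decay with t
  tt <- seq(300, 3600, by = 300)
  tr <- list(vial_id = 1, times_s = c(0, tt),
             position_mm = c(0, 2 * (tt / 3600)^0.4),
             flags = rep("ok", length(tt) + 1))
  fit <- fit_front(tr)
  expect_true(all(diff(fit$per_time$d_pseudo_m2_s) < 0))
})

test_that("noisy sqrt-t tracks are recovered to a few percent", {
  set.seed(202)
  D <- 11.55e-9
  mm_per_px <- 0.0681
  tt <- seq(300, 1200, by = 300)
  est <- replicate(20, {
    d_mm <- front_position(tt, D) * 1000 + rnorm(length(tt), 0, mm_per_px)
    fit_front(list(vial_id = 1, times_s = c(0, tt),
                   position_mm = c(0, d_mm),
                   flags = rep("ok", length(tt) + 1)))$fitted_D
  })
  rel_err <- abs(est - D) / D
  expect_lt(median(rel_err), 0.05)
  expect_lt(abs(mean(est) - D) / D, 0.02)
})

test_that("replicate summaries average per-vial means with a sample sd", {
  f1 <- fit_front(exact_track(3e-9))
  f2 <- fit_front(exact_track(5e-9))
  s <- summarize_replicates(list(f1, f2), "demo")
  expect_equal(s$n, 2L)
  expect_equal(s$mean_D, 4e-9, tolerance = 1e-12)
  expect_equal(s$sd_D, sqrt(2) * 1e-9, tolerance = 1e-9)
  expect_equal(s$per_vial_D, c(3e-9, 5e-9), tolerance = 1e-12)
  single <- summarize_replicates(f1)
  expect_equal(single$sd_D, 0)
  expect_error(summarize_replicates(list()), "no fits")
})

test_that("front_fit methods behave as a standard modelling object", {
  fit <- fit_front(exact_track(4e-9))
  expect_output(print(fit), "fitted D")
  expect_output(print(summary(fit)), "per-time D_pseudo range")
  # predict: sqrt-law positions at new times
  expect_equal(predict(fit, 900), front_position(900, fit$fitted_D))
  expect_equal(predict(fit), front_position(fit$per_time$time_s,
                                            fit$fitted_D))
  sims <- simulate(fit, nsim = 3, seed = 9)
  expect_identical(dim(sims), c(4L, 3L))
  expect_identical(simulate(fit, nsim = 3, seed = 9), sims)
  expect_true(all(sims >= 0))
  pdf(NULL)
  expect_invisible(plot(fit))
  dev.off()
})
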