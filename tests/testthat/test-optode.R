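test_that("ratio images divide red by green and mask weak reference pixels", {
  g <- matrix(0.5, 3, 3)
  f <- rgb_frame(g, g, g)
  expect_equal(ratio_image(f)$data, matrix(1, 3, 3))
  f2 <- rgb_frame(2 * g, g, g)
  expect_equal(ratio_image(f2)$data, matrix(2, 3, 3))
  g0 <- g; g0[2, 2] <- 0
  r <- ratio_image(rgb_frame(g, g0, g))
  expect_true(is.na(r$data[2, 2]))
  expect_equal(sum(is.na(r$data)), 1L)
  # green below the floor (1% of dynamic range by default) is masked too
  gf <- g; gf[1, 3] <- 0.005
  expect_true(is.na(ratio_image(rgb_frame(g, gf, g))$data[1, 3]))
})

test_that("delta ratio references to the dark-anoxic state and grows masks", {
  r <- scalar_image(matrix(0.6, 3, 3), "ratio")
  rd <- scalar_image(matrix(0.9, 3, 3), "ratio")
  expect_equal(delta_ratio(r, r)$data, matrix(0, 3, 3))
  expect_equal(delta_ratio(r, rd)$data, matrix(0.3, 3, 3))
  r2 <- r; r2$data[1, 1] <- NA
  rd2 <- rd; rd2$data[3, 3] <- NA
  dr <- delta_ratio(r2, rd2)
  expect_true(is.na(dr$data[1, 1]) && is.na(dr$data[3, 3]))
  expect_equal(sum(is.na(dr$data)), 2L)
  expect_error(delta_ratio(r, scalar_image(matrix(1, 2, 2))), "co-registered")
})

test_that("dark reference averages late dark frames only", {
  g <- matrix(0.5, 2, 2)
  mk <- function(rr, t, light) rgb_frame(matrix(rr, 2, 2), g, g, t, light)
  frames <- list(mk(0.50, 0, "nir_on"), mk(0.40, 40, "dark"),
                 mk(0.45, 45, "dark"), mk(0.47, 50, "dark"))
  ref <- dark_reference(frames)
  expect_equal(ref$data, matrix(mean(c(0.45, 0.47) / 0.5), 2, 2))
  expect_equal(attr(ref, "n_frames"), 2L)
  expect_error(dark_reference(frames, min_dark_minutes = 60), "no dark frames")
})

test_that("calibration fit recovers exact and noisy parameters", {
  # noiseless forward model -> parameters back to 1e-6 relative
  pairs <- synth_calibration_series(a = 0.8, b = 0.05, sigma = 0, seed = 1)
  m <- fit_calibration(pairs)
  expect_equal(m$a, 0.8, tolerance = 1e-6)
  expect_equal(m$b, 0.05, tolerance = 1e-6)
  expect_lt(m$rss, 1e-12)
  # the model family passes through (0, 0) by construction
  expect_equal(predict(m, 0), 0)
  # noisy series (sigma = 0.01, 8 levels, fixed seed) -> within 5% of truth
  noisy <- synth_calibration_series(a = 0.8, b = 0.05, sigma = 0.01, seed = 3)
  mn <- fit_calibration(noisy)
  expect_lt(abs(mn$a - 0.8) / 0.8, 0.05)
  expect_lt(abs(mn$b - 0.05) / 0.05, 0.05)
  # validation
  expect_error(fit_calibration(pairs[1:2, ]), ">= 3 points")
  flat <- data.frame(o2_percent = c(50, 50, 50), delta_r = c(.1, .2, .3))
  expect_error(fit_calibration(flat), "distinct")
  far <- data.frame(o2_percent = c(50, 80, 100), delta_r = c(.5, .7, .75))
  expect_warning(fit_calibration(far), "anoxia")
})

test_that("calibration inversion is the exact inverse below the clamp", {
  m <- calibration_model(a = 0.8, b = 0.05)
  cvals <- c(0, 0.5, 5, 20, 50, 100, 149)
  dr <- scalar_image(matrix(m$a * (1 - exp(-m$b * cvals)), 1, length(cvals)),
                     "delta_ratio")
  o2 <- invert_calibration(m, dr)
  expect_equal(as.vector(o2$data), cvals, tolerance = 1e-9)
  expect_false(any(o2$clamped))
  # monotonicity below the clamp
  expect_true(all(diff(as.vector(o2$data)) > 0))
  # dR at/above the asymptote clamps and flags; negatives clamp to 0
  dr2 <- scalar_image(matrix(c(-0.1, 0.85), 1, 2), "delta_ratio")
  o22 <- invert_calibration(m, dr2, eps = 1e-6, cap_percent = Inf)
  expect_equal(o22$data[1, 1], 0)
  expect_equal(o22$data[1, 2], -log(1e-6) / m$b)
  expect_true(all(o22$clamped))
  # cap rule
  o23 <- invert_calibration(m, dr2, cap_percent = 150)
  expect_equal(o23$data[1, 2], 150)
})

test_that("seawater O2 solubility and density match published check values", {
  # Garcia & Gordon (1992) combined fit check value, 10 C / S = 35
  expect_equal(o2_saturation_umol_kg(10, 35), 274.610, tolerance = 1e-5)
  # Millero & Poisson (1981) check value, 5 C / S = 35
  expect_equal(seawater_density(5, 35), 1027.67547, tolerance = 1e-7)
  # conversion is linear in % air saturation and zero at anoxia
  expect_equal(airsat_to_concentration(0, 23, 35), 0)
  expect_equal(airsat_to_concentration(50, 23, 35),
               airsat_to_concentration(100, 23, 35) / 2)
  # 23 C / S = 35: ~219 umol/L at air saturation
  expect_equal(airsat_to_concentration(100, 23, 35), 219.04, tolerance = 1e-4)
  expect_error(airsat_to_concentration(50, 60, 35), "temperature")
  expect_error(airsat_to_concentration(50, 23, 80), "salinity")
})

test_that("masks only grow along the optode pipeline", {
  p <- optode_params(nrow = 12, ncol = 12, snr = 80, seed = 5)
  sim <- synth_optode_timeseries(p)
  f <- sim$frames[[1]]
  f$green[3, 3] <- 0                      # dead reference pixel
  r <- ratio_image(f)
  rdk <- dark_reference(sim$frames)
  dr <- delta_ratio(r, rdk)
  o2 <- invert_calibration(calibration_model(0.8, 0.05), dr)
  m1 <- is.na(r$data); m2 <- is.na(dr$data); m3 <- is.na(o2$data)
  expect_true(all(m1 <= m2))
  expect_true(all(m2 <= m3))
  expect_true(m3[3, 3])
})
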