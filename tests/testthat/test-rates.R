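# build a tiny o2 series directly from % air saturation matrices
mk_series <- function(mats, times, events) {
  frames <- Map(function(m, t) {
    structure(list(data = m, t = t, light = NA_character_,
                   clamped = matrix(FALSE, nrow(m), ncol(m)),
                   saturated = matrix(FALSE, nrow(m), ncol(m))),
              class = "o2_image")
  }, mats, times)
  o2_series(frames, events)
}

umolL <- airsat_to_concentration(1, 23, 35)  # umol/L per % air sat

test_that("rate images are finite differences over actual frame spacing", {
  m0 <- matrix(10, 2, 2)
  ev <- data.frame(t_min = 5, event = "light_on")
  # identical frames -> zero rate
  s0 <- mk_series(list(m0, m0), c(0, 5.5), ev)
  expect_equal(rate_image(s0, 5)$data, matrix(0, 2, 2))
  # 10 umol/L rise over 5 min -> 2 umol/L/min
  rise <- m0 + 10 / umolL
  s1 <- mk_series(list(m0, rise), c(2.5, 7.5), ev)
  r1 <- rate_image(s1, 5)
  expect_equal(r1$data, matrix(2, 2, 2), tolerance = 1e-12)
  expect_identical(r1$units, "umol_O2_per_L_per_min")
  expect_equal(attr(r1, "dt_min"), 5)
  # dt read from timestamps, not assumed: same frames 2 min apart -> 5 umol/L/min
  s2 <- mk_series(list(m0, rise), c(4, 6), ev)
  expect_equal(rate_image(s2, 5)$data, matrix(5, 2, 2), tolerance = 1e-12)
  # missing bracketing frame errors with the event time
  expect_error(rate_image(s1, 8), "t = 8")
})

test_that("time reversal negates the rate map", {
  a <- matrix(runif(9, 0, 50), 3, 3)
  b <- matrix(runif(9, 0, 50), 3, 3)
  ev <- data.frame(t_min = 5, event = "light_on")
  fwd <- rate_image(mk_series(list(a, b), c(0, 10), ev), 5)
  rev <- rate_image(mk_series(list(b, a), c(0, 10), ev), 5)
  expect_equal(rev$data, -fwd$data)
})

test_that("respiration and net photosynthesis pick the right events", {
  c_hi <- matrix(40, 2, 2); c_lo <- matrix(20, 2, 2)
  events <- data.frame(t_min = c(5, 15), event = c("light_off", "light_on"))
  s <- mk_series(list(c_hi, c_lo, c_lo, c_hi), c(0.5, 10.5, 14.5, 19.5), events)
  rd <- suppressWarnings(dark_respiration(s))
  pn <- net_photosynthesis(s)
  p <- 20 * umolL / 5   # 20 % airsat over 5 min (frames at 14.5 and 19.5)
  expect_equal(rd$data, matrix(-20 * umolL / 10, 2, 2), tolerance = 1e-12)
  expect_equal(pn$data, matrix(p, 2, 2), tolerance = 1e-12)
  # symmetric production/consumption gives mirrored maps
  s_sym <- mk_series(list(c_hi, c_lo, c_hi), c(0, 5, 10) + 0.5,
                     data.frame(t_min = c(1, 6), event = c("light_off", "light_on")))
  rd2 <- dark_respiration(s_sym); pn2 <- net_photosynthesis(s_sym)
  expect_equal(pn2$data, -rd2$data)
  # constant dark series -> zero respiration
  s_const <- mk_series(list(c_lo, c_lo), c(0, 5),
                       data.frame(t_min = 2, event = "light_off"))
  expect_equal(dark_respiration(s_const)$data, matrix(0, 2, 2))
  # no event of the requested type
  expect_error(net_photosynthesis(s_const), "no light_on")
  # multiple events: earliest by default, selectable by index
  s_two <- mk_series(list(c_lo, c_hi, c_hi, matrix(60, 2, 2)),
                     c(0, 5, 10, 15),
                     data.frame(t_min = c(2, 12),
                                event = c("light_on", "light_on")))
  expect_equal(net_photosynthesis(s_two)$data, matrix(20 * umolL / 5, 2, 2))
  expect_equal(net_photosynthesis(s_two, which_event = 2)$data,
               matrix(20 * umolL / 5, 2, 2))
})

test_that("gross photosynthesis is net plus respiration magnitude, pixelwise", {
  pn <- scalar_image(matrix(3, 2, 2), "umol_O2_per_L_per_min")
  rd <- scalar_image(matrix(-2, 2, 2), "umol_O2_per_L_per_min")
  expect_equal(gross_photosynthesis(pn, rd)$data, matrix(5, 2, 2))
  zero <- scalar_image(matrix(0, 2, 2), "umol_O2_per_L_per_min")
  expect_equal(gross_photosynthesis(pn, zero)$data, pn$data)
  expect_equal(gross_photosynthesis(zero, scalar_image(matrix(-4, 2, 2),
                                                       "umol_O2_per_L_per_min"))$data,
               matrix(4, 2, 2))
  expect_error(gross_photosynthesis(pn, scalar_image(matrix(1, 3, 3),
                                                     "umol_O2_per_L_per_min")),
               "co-registered")
  expect_error(gross_photosynthesis(pn, scalar_image(matrix(1, 2, 2), "ratio")),
               "units")
  # bundled maps satisfy the identity exactly on random inputs
  rnd_pn <- scalar_image(matrix(rnorm(64), 8, 8), "umol_O2_per_L_per_min")
  rnd_rd <- scalar_image(matrix(rnorm(64, -1), 8, 8), "umol_O2_per_L_per_min")
  rm_ <- rate_maps(rnd_rd, rnd_pn)
  expect_identical(rm_$p_gross$data, rnd_pn$data + abs(rnd_rd$data))
})

test_that("roi statistics use population SD over unmasked pixels", {
  v <- matrix(0, 4, 4); v[1, 1] <- 2; v[1, 2] <- 4
  maps <- rate_maps(scalar_image(-v, "umol_O2_per_L_per_min"),
                    scalar_image(v, "umol_O2_per_L_per_min"))
  roi_pair <- matrix(FALSE, 4, 4); roi_pair[1, 1:2] <- TRUE
  roi_one <- matrix(FALSE, 4, 4); roi_one[1, 1] <- TRUE
  st <- roi_statistics(maps, list(pair = roi_pair, one = roi_one))
  expect_equal(st$pn_mean, c(3, 2))
  expect_equal(st$pn_sd, c(1, 0))   # population SD: {2,4} -> 1; n = 1 -> 0
  expect_equal(st$rd_mean, c(-3, -2))
  expect_equal(st$pg_mean, c(6, 4))
  expect_equal(st$n_pixels, c(2L, 1L))
  # uniform map -> SD 0 everywhere
  u <- rate_maps(scalar_image(matrix(-1, 4, 4), "umol_O2_per_L_per_min"),
                 scalar_image(matrix(2, 4, 4), "umol_O2_per_L_per_min"))
  stu <- roi_statistics(u, list(all = matrix(TRUE, 4, 4)))
  expect_equal(c(stu$rd_sd, stu$pn_sd, stu$pg_sd), c(0, 0, 0))
  # labelled-matrix input is equivalent to a mask list
  lab <- matrix(0L, 4, 4); lab[1, 1:2] <- 1L; lab[3, ] <- 2L
  st2 <- roi_statistics(maps, lab)
  expect_equal(nrow(st2), 2L)
  expect_equal(st2$pn_mean[1], 3)
  expect_error(roi_statistics(maps, list(bad = matrix(FALSE, 4, 4))), "empty")
  masked <- maps; masked$r_dark$data[2, 2] <- NA
  roi_m <- matrix(FALSE, 4, 4); roi_m[2, 2] <- TRUE
  expect_error(roi_statistics(masked, list(m = roi_m)), "masked")
})

test_that("areal scale-up reproduces the printed unit chain and is linear", {
  ref <- areal_rate(10, 0.4, 0.1)
  expect_identical(ref$value, 10 * 0.4 * 0.1 * 1e-6 * 1e4 * 60)
  expect_equal(ref$value, 0.24)
  expect_equal(areal_rate(0, 0.4, 0.1)$value, 0)
  expect_equal(areal_rate(5, 0.4, 0.1)$value, 0.12)
  # linear in every argument
  expect_equal(areal_rate(20, 0.4, 0.1)$value, 2 * ref$value)
  expect_equal(areal_rate(10, 0.2, 0.1)$value, ref$value / 2)
  expect_equal(areal_rate(10, 0.4, 0.3)$value, 3 * ref$value)
  expect_error(areal_rate(10, 0, 0.1), "porosity")
  expect_error(areal_rate(10, 1.5, 0.1), "porosity")
  expect_error(areal_rate(10, 0.4, -1), "thickness")
})

test_that("NIR fraction is a guarded percentage", {
  expect_equal(nir_fraction(0.24, 10), 2.4)
  expect_equal(nir_fraction(3, 3), 100)
  expect_equal(nir_fraction(0, 10), 0)
  expect_equal(nir_fraction(areal_rate(10, 0.4, 0.1), 10), 2.4)
  expect_error(nir_fraction(0.24, 0), "positive")
})
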