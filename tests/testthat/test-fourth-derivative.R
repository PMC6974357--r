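test_that("filter annihilates polynomials up to cubic for all valid settings", {
  wl <- seq(400, 800, by = 4)
  poly <- 3 + 0.1 * wl - 2e-4 * wl^2 + 2e-7 * wl^3
  cube <- uniform_cube(wl, poly)
  for (cfg in list(c(9, 5), c(11, 5), c(13, 6), c(21, 5))) {
    dv <- spectral_fourth_derivative(cube, window = cfg[1], polyorder = cfg[2])
    expect_lt(max(abs(dv$data), na.rm = TRUE), 1e-10)
    # edge bands are masked
    h <- (cfg[1] - 1) / 2
    expect_true(all(is.na(dv$data[seq_len(h), , ])))
    expect_false(anyNA(dv$data[seq(h + 1, length(wl) - h), , ]))
  }
})

test_that("filter is exact on lambda^4 (constant fourth derivative 24)", {
  wl <- seq(400, 500, by = 2)
  cube <- spectral_cube(wl,
                        array(rep(((wl - 400) / 100)^4, 4),
                              c(length(wl), 2, 2)),
                        "reflectance")
  dv <- spectral_fourth_derivative(cube)
  # d4/dl4 ((l - 400)/100)^4 = 24 / 100^4
  expect_equal(max(dv$data, na.rm = TRUE), 24 / 1e8, tolerance = 1e-6)
  expect_equal(min(dv$data, na.rm = TRUE), 24 / 1e8, tolerance = 1e-6)
})

test_that("a Gaussian reflectance dip matches its analytic fourth derivative", {
  wl <- seq(600, 840, by = 1)
  spec <- 100 * (1 - 0.5 * gauss(wl, 720, 10))
  cube <- uniform_cube(wl, spec, nrow = 2, ncol = 2)
  dv <- spectral_fourth_derivative(cube)
  prof <- -dv$data[, 1, 1]             # absorption-positive convention
  truth <- gauss_d4(wl, 720, 10, 50)   # closed form for the 50%-of-100 dip
  expect_equal(wl[which.max(prof)], 720)          # maximal at dip centre
  expect_equal(max(prof, na.rm = TRUE), truth[wl == 720], tolerance = 0.05)
  ii <- !is.na(prof) & abs(wl - 720) < 40
  rel_rmse <- sqrt(mean((prof[ii] - truth[ii])^2)) / max(abs(truth[ii]))
  expect_lt(rel_rmse, 0.03)
})

test_that("validation rejects bad settings and non-uniform grids", {
  wl <- seq(400, 500, by = 2)
  cube <- uniform_cube(wl, rep(10, length(wl)))
  expect_error(spectral_fourth_derivative(cube, window = 8), "odd")
  expect_error(spectral_fourth_derivative(cube, polyorder = 3), ">= 4")
  expect_error(spectral_fourth_derivative(cube, window = 5, polyorder = 5),
               "exceed")
  expect_error(spectral_fourth_derivative(
    uniform_cube(wl[1:7], rep(10, 7))), "fewer bands")
  bad <- uniform_cube(c(wl[1:20], wl[21:51] + 3), rep(10, 51))
  expect_error(spectral_fourth_derivative(bad), "uniform")
})

test_that("band amplitudes are invariant to cubic baselines and separate bands", {
  wl <- seq(600, 840, by = 2)
  depth_map <- matrix(c(0, 0.1, 0.25, 0.4, 0.55, 0.7), 2, 3)
  mk_cube <- function(baseline) {
    data <- array(0, c(length(wl), 2, 3))
    for (i in 1:2) for (j in 1:3) {
      data[, i, j] <- baseline + 60 * (1 - depth_map[i, j] * gauss(wl, 720, 10))
    }
    spectral_cube(wl, data, "reflectance")
  }
  flat <- band_amplitude_map(
    spectral_fourth_derivative(mk_cube(rep(0, length(wl)))),
    band_window(718, 722))
  tilted <- band_amplitude_map(
    spectral_fourth_derivative(mk_cube(5 + 0.02 * wl - 1e-5 * wl^2)),
    band_window(718, 722))
  expect_equal(tilted$data, flat$data, tolerance = 1e-8)
  # amplitude scales with the true dip depth: perfect rank agreement
  expect_equal(cor(as.vector(flat$data), as.vector(depth_map),
                   method = "spearman"), 1)
  # zero derivative -> zero map
  zero <- uniform_cube(wl, rep(50, length(wl)))
  expect_equal(
    band_amplitude_map(spectral_fourth_derivative(zero),
                       band_window(718, 722))$data,
    matrix(0, 3, 3))
  # a 675-nm-only dip leaves the chlorophyll f band empty
  only_a <- uniform_cube(wl, 60 * (1 - 0.4 * gauss(wl, 675, 6)))
  dv <- spectral_fourth_derivative(only_a)
  in_f <- band_amplitude_map(dv, band_window(718, 722))$data
  in_a <- band_amplitude_map(dv, band_window(670, 680))$data
  expect_gt(min(in_a), 1e-4)
  expect_lt(max(in_f), 1e-6 * max(in_a))
  expect_error(band_amplitude_map(dv, band_window(900, 950)), "outside")
})

test_that("abundance scaling maps [0, clip percentile] onto [0, 1]", {
  m <- scalar_image(matrix(c(0, 1, 2, 3, 100), 1, 5))
  out <- normalize_abundance(m, clip_pct = 100)
  expect_equal(out$data, matrix(c(0, .01, .02, .03, 1), 1, 5))
  expect_identical(out$units, "relative_0_1")
  # constant positive map -> all ones; all-zero map -> stays zero
  expect_equal(normalize_abundance(scalar_image(matrix(5, 2, 2)))$data,
               matrix(1, 2, 2))
  expect_equal(normalize_abundance(scalar_image(matrix(0, 2, 2)))$data,
               matrix(0, 2, 2))
  # clipping saturates hot pixels at 1 and preserves order below the clip
  hot <- matrix(c(seq(0, 1, length.out = 99), 50), 10, 10)
  out2 <- normalize_abundance(scalar_image(hot), clip_pct = 99)
  expect_true(all(out2$data >= 0 & out2$data <= 1))
  expect_equal(order(hot[hot < max(hot)]), order(out2$data[hot < max(hot)]))
})

test_that("threshold overlay paints chlorophyll classes with red precedence", {
  base <- rgb_frame(matrix(.5, 4, 4), matrix(.5, 4, 4), matrix(.5, 4, 4))
  zero <- scalar_image(matrix(0, 4, 4))
  # both maps zero -> untouched image
  out0 <- pigment_overlay(base, zero, zero, .1, .1)
  expect_equal(out0$red, base$red)
  expect_equal(out0$green, base$green)
  chla <- scalar_image(matrix(c(rep(1, 8), rep(0, 8)), 4, 4))
  hot <- matrix(0, 4, 4); hot[1:2, 1:2] <- 1
  chlf <- scalar_image(hot)
  out <- pigment_overlay(base, chla, chlf, .5, .5)
  # chlorophyll f mask rendered red, wins where both exceed threshold
  expect_true(all(out$red[hot == 1] == 1 & out$green[hot == 1] == 0))
  only_a <- chla$data > .5 & hot == 0
  expect_true(all(out$green[only_a] == 1 & out$red[only_a] == 0))
  expect_true(all(out$red[chla$data == 0 & hot == 0] == .5))
  expect_error(pigment_overlay(base, scalar_image(matrix(0, 2, 2)), chlf,
                               .5, .5), "co-registered")
})

test_that("emission band maps separate fluorescent populations", {
  wl <- seq(620, 780, by = 5)
  # population 1 emits at 650-660 (phycobiliprotein), population 2 at 740-750
  data <- array(0, c(length(wl), 2, 2))
  data[, 1, ] <- 10 * gauss(wl, 655, 5)
  data[, 2, ] <- 10 * gauss(wl, 745, 5)
  fl <- spectral_cube(wl, data, "fluorescence")
  bands <- list(red = band_window(740, 750), blue = band_window(650, 660))
  out <- emission_band_map(fl, bands)
  expect_true(all(out$red[2, ] > 0.9) && all(out$red[1, ] < 1e-6))
  expect_true(all(out$blue[1, ] > 0.9) && all(out$blue[2, ] < 1e-6))
  expect_equal(out$green, matrix(0, 2, 2))
  # flat spectrum -> equal channels
  flat <- spectral_cube(wl, array(3, c(length(wl), 2, 2)), "fluorescence")
  outf <- emission_band_map(flat, bands)
  expect_equal(outf$red, outf$blue)
  expect_error(emission_band_map(fl, list(red = band_window(900, 910))),
               "outside")
  expect_error(
    emission_band_map(uniform_cube(wl, rep(1, length(wl))), bands),
    "fluorescence")
})
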