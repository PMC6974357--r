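# shared fixture builders (everything is generated in code; no data files)

# cube with the same spectrum at every pixel
uniform_cube <- function(wavelengths, spectrum, nrow = 3, ncol = 3,
                         kind = "reflectance") {
  spectral_cube(wavelengths,
                array(rep(spectrum, nrow * ncol),
                      c(length(wavelengths), nrow, ncol)),
                kind)
}

gauss <- function(lambda, center, sigma) {
  exp(-(lambda - center)^2 / (2 * sigma^2))
}

# analytic 4th derivative of depth * gauss(lambda) (the negated-derivative
# profile of a reflectance dip of that depth)
gauss_d4 <- function(lambda, center, sigma, depth) {
  z <- (lambda - center) / sigma
  depth * exp(-z^2 / 2) * (z^4 - 6 * z^2 + 3) / sigma^4
}

# exact o2_calibration object without fitting
calibration_model <- function(a, b) {
  structure(list(a = a, b = b, rss = 0, n = 0, fit = NULL),
            class = "o2_calibration")
}

# pigment pipeline on a generated scene, returning the chlorophyll f map
scene_chlf_map <- function(scene, window = 9, statistic = "max") {
  pigment_pipeline(scene$raw, scene$dark, scene$standard,
                   window = window, statistic = statistic)$chlf
}
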