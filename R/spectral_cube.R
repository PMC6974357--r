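#' Spectral image cube
#'
#' Container for a hyperspectral image stack: one image plane per wavelength
#' band, stored as a `wavelength x row x column` array together with a
#' strictly increasing wavelength vector in nm.
#'
#' @param wavelengths Numeric vector of band-centre wavelengths in nm,
#'   strictly increasing.
#' @param data Numeric array with `dim = c(length(wavelengths), nrow, ncol)`.
#'   Reflectance cubes are expressed in % reflectance (nominally 0--100;
#'   larger values are permitted but flagged with a warning).
#' @param kind One of `"raw"`, `"dark_corrected"`, `"reflectance"`,
#'   `"fluorescence"`, `"derivative"`.
#'
#' @return An object of class `spectral_cube`: a list with elements
#'   `wavelengths`, `data` and `kind`.
#' @examples
#' cube <- spectral_cube(seq(400, 800, 50), array(1, c(9, 4, 4)), "raw")
#' dim(cube$data)
#' @export
spectral_cube <- function(wavelengths, data,
                          kind = c("raw", "dark_corrected", "reflectance",
                                   "fluorescence", "derivative")) {
  kind <- match.arg(kind)
  wavelengths <- as.numeric(wavelengths)
  if (length(wavelengths) < 2L || any(diff(wavelengths) <= 0)) {
    stop("`wavelengths` must be strictly increasing with length >= 2")
  }
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("`data` must be a 3-d array (wavelength x row x column)")
  }
  if (dim(data)[1] != length(wavelengths)) {
    stop("first dimension of `data` (", dim(data)[1],
         ") does not match length of `wavelengths` (", length(wavelengths), ")")
  }
  if (kind != "derivative" && any(data < 0, na.rm = TRUE)) {
    stop("cube intensities must be nonnegative")
  }
  if (kind == "reflectance" && any(data > 100, na.rm = TRUE)) {
    warning("reflectance values above 100% present (",
            sum(data > 100, na.rm = TRUE), " voxels)")
  }
  structure(list(wavelengths = wavelengths, data = data, kind = kind),
            class = "spectral_cube")
}

#' @export
print.spectral_cube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<spectral_cube> %s, %d bands (%.1f-%.1f nm), %d x %d pixels\n",
              x$kind, d[1], min(x$wavelengths), max(x$wavelengths), d[2], d[3]))
  invisible(x)
}

#' @export
dim.spectral_cube <- function(x) dim(x$data)

#' Wavelength band window
#'
#' A closed interval of wavelengths, used to pool fourth-derivative
#' amplitudes over a pigment absorption band (e.g. 670--680 nm for
#' chlorophyll a, 718--722 nm for chlorophyll f).
#'
#' @param lo,hi Band limits in nm, `lo <= hi`.
#' @return An object of class `band_window`.
#' @export
band_window <- function(lo, hi) {
  stopifnot(is.numeric(lo), is.numeric(hi), length(lo) == 1L, length(hi) == 1L)
  if (lo > hi) stop("band window requires lo <= hi")
  structure(list(lo = lo, hi = hi), class = "band_window")
}

#' @export
print.band_window <- function(x, ...) {
  cat(sprintf("<band_window> %.1f-%.1f nm\n", x$lo, x$hi))
  invisible(x)
}

# index of the sampled band nearest to `nm`; lower wavelength wins exact ties
nearest_band <- function(wavelengths, nm, tol = Inf) {
  d <- abs(wavelengths - nm)
  i <- which.min(d)  # which.min returns the first (lower-wavelength) minimum
  if (d[i] > tol) {
    stop(sprintf("no sampled band within %.1f nm of %.1f nm", tol, nm))
  }
  i
}

# indices covered by a band window after snapping endpoints to sampled bands
band_indices <- function(wavelengths, band) {
  if (band$hi < min(wavelengths) || band$lo > max(wavelengths)) {
    stop(sprintf("band %.1f-%.1f nm outside sampled range %.1f-%.1f nm",
                 band$lo, band$hi, min(wavelengths), max(wavelengths)))
  }
  i_lo <- nearest_band(wavelengths, band$lo)
  i_hi <- nearest_band(wavelengths, band$hi)
  seq(i_lo, i_hi)
}

#' Scalar image with a units tag
#'
#' @param data Numeric matrix; masked pixels are `NA`.
#' @param units Character units tag (e.g. `"percent_reflectance"`,
#'   `"relative_0_1"`, `"percent_airsat"`, `"umol_O2_per_L_per_min"`).
#' @return An object of class `scalar_image`.
#' @export
scalar_image <- function(data, units = "dimensionless") {
  if (!is.matrix(data)) stop("`data` must be a matrix")
  if (any(is.infinite(data))) stop("scalar image values must be finite or NA")
  structure(list(data = data, units = units), class = "scalar_image")
}

#' @export
print.scalar_image <- function(x, ...) {
  rng <- range(x$data, na.rm = TRUE)
  cat(sprintf("<scalar_image> %d x %d [%s], range %.4g..%.4g, %d masked\n",
              nrow(x$data), ncol(x$data), x$units, rng[1], rng[2],
              sum(is.na(x$data))))
  invisible(x)
}

#' Three-channel image frame
#'
#' RGB frame as produced by the optode camera or by [rgb_composite()].
#' The optode sensing chemistry uses the red (O2-sensitive indicator) and
#' green (reference dye) channels; blue is carried along but ignored by the
#' ratiometric pipeline.
#'
#' @param red,green,blue Numeric matrices of identical dimension.
#' @param t Acquisition time in minutes since experiment start (`NA` for
#'   frames without a timeline, e.g. composites).
#' @param light Illumination state, `"nir_on"` or `"dark"` (`NA` allowed).
#' @return An object of class `rgb_frame`.
#' @export
rgb_frame <- function(red, green, blue, t = NA_real_, light = NA_character_) {
  if (!is.matrix(red) || !identical(dim(red), dim(green)) ||
      !identical(dim(red), dim(blue))) {
    stop("red, green and blue must be matrices of identical dimension")
  }
  if (any(c(red, green, blue) < 0, na.rm = TRUE)) {
    stop("channel intensities must be nonnegative")
  }
  if (!is.na(t) && !is.finite(t)) stop("`t` must be finite or NA")
  if (!is.na(light)) light <- match.arg(light, c("nir_on", "dark"))
  structure(list(red = red, green = green, blue = blue,
                 t = t, light = light), class = "rgb_frame")
}

#' @export
print.rgb_frame <- function(x, ...) {
  cat(sprintf("<rgb_frame> %d x %d, t = %s min, light = %s\n",
              nrow(x$red), ncol(x$red),
              format(x$t), ifelse(is.na(x$light), "NA", x$light)))
  invisible(x)
}
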