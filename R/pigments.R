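#' Dark-correct a hyperspectral stack
#'
#' Subtracts a dark (shutter-closed) stack from a raw stack, clipping
#' negative differences at zero.
#'
#' @param raw,dark `spectral_cube` objects with identical wavelength vectors
#'   and dimensions.
#' @return A `spectral_cube` with `kind = "dark_corrected"`.
#' @export
dark_correct <- function(raw, dark) {
  stopifnot(inherits(raw, "spectral_cube"), inherits(dark, "spectral_cube"))
  if (!identical(dim(raw$data), dim(dark$data))) {
    stop("raw and dark cubes differ in shape")
  }
  if (!isTRUE(all.equal(raw$wavelengths, dark$wavelengths))) {
    stop("raw and dark cubes differ in wavelength vectors")
  }
  spectral_cube(raw$wavelengths, pmax(raw$data - dark$data, 0),
                kind = "dark_corrected")
}

#' Convert a dark-corrected stack to % reflectance
#'
#' Normalises a dark-corrected sample stack against a dark-corrected stack of
#' a calibrated reflectance standard (default 20% reflectance). The standard
#' stack is spatially averaged to a single per-wavelength reference spectrum
#' before division, since the standard is imaged separately and cannot be
#' registered per pixel.
#'
#' @param sample Dark-corrected `spectral_cube` of the specimen.
#' @param standard Dark-corrected `spectral_cube` of the reflectance standard,
#'   same wavelength vector as `sample`.
#' @param standard_pct Nominal reflectance of the standard in % (default 20).
#' @return A `spectral_cube` with `kind = "reflectance"` in units of
#'   % reflectance. Wavelengths at which the reference spectrum is zero are
#'   masked (`NA`) with a warning.
#' @export
to_reflectance <- function(sample, standard, standard_pct = 20) {
  stopifnot(inherits(sample, "spectral_cube"), inherits(standard, "spectral_cube"))
  if (sample$kind != "dark_corrected" || standard$kind != "dark_corrected") {
    stop("both cubes must be dark-corrected (see dark_correct())")
  }
  if (!isTRUE(all.equal(sample$wavelengths, standard$wavelengths))) {
    stop("sample and standard cubes differ in wavelength vectors")
  }
  ref <- apply(standard$data, 1, mean, na.rm = TRUE)
  bad <- !is.finite(ref) | ref == 0
  if (any(bad)) {
    warning(sum(bad), " wavelength(s) with zero standard reference masked")
    ref[bad] <- NA_real_
  }
  refl <- standard_pct * sweep(sample$data, 1, ref, "/")
  out <- spectral_cube(sample$wavelengths, refl, kind = "reflectance")
  out
}

#' Construct an RGB composite from a reflectance cube
#'
#' Picks the sampled band nearest each requested wavelength (default
#' 650/550/450 nm for R/G/B, i.e. a true-colour rendering) and rescales each
#' channel independently to the 0--1 display range. The per-channel scale
#' factors (the channel maxima before rescaling) are recorded in the
#' `"scales"` attribute.
#'
#' @param cube Reflectance `spectral_cube`.
#' @param r,g,b Requested wavelengths in nm.
#' @param tol Maximum distance in nm between a requested wavelength and the
#'   nearest sampled band (default 5); exceeding it is an error. The lower
#'   wavelength wins exact ties.
#' @return An `rgb_frame` with channels in `[0, 1]`.
#' @export
rgb_composite <- function(cube, r = 650, g = 550, b = 450, tol = 5) {
  stopifnot(inherits(cube, "spectral_cube"))
  if (cube$kind != "reflectance") stop("rgb_composite expects a reflectance cube")
  idx <- vapply(c(r, g, b), function(nm) nearest_band(cube$wavelengths, nm, tol),
                integer(1))
  chan <- lapply(idx, function(i) cube$data[i, , ])
  scales <- vapply(chan, function(m) {
    mx <- max(m, na.rm = TRUE)
    if (!is.finite(mx) || mx <= 0) 1 else mx
  }, numeric(1))
  chan <- Map(function(m, s) pmin(m / s, 1), chan, scales)
  out <- rgb_frame(chan[[1]], chan[[2]], chan[[3]])
  attr(out, "scales") <- scales
  attr(out, "bands_nm") <- cube$wavelengths[idx]
  out
}

#' Per-pixel fourth derivative of spectra
#'
#' Computes the fourth derivative of each pixel spectrum with respect to
#' wavelength by Savitzky-Golay polynomial filtering. Narrow absorption bands
#' survive differentiation while smooth baselines (any polynomial of degree
#' <= `polyorder - 1`, in particular all cubics) are annihilated exactly,
#' which is the rationale for derivative spectroscopy on scattering samples.
#'
#' The wavelength grid must be uniform (Savitzky-Golay assumes equal
#' spacing). The `floor(window/2)` bands at each spectral edge are masked.
#'
#' @param cube A `spectral_cube` (typically reflectance).
#' @param window Odd filter window length in bands (default 9).
#' @param polyorder Polynomial order of the local fit (default 5); must be
#'   >= 4 and < `window`.
#' @return A `spectral_cube` of `kind = "derivative"` holding
#'   d4(value)/d(lambda)4 in (cube units) nm^-4, with attribute
#'   `"deriv_order" = 4`.
#' @export
spectral_fourth_derivative <- function(cube, window = 9, polyorder = 5) {
  stopifnot(inherits(cube, "spectral_cube"))
  if (window %% 2 != 1) stop("`window` must be odd")
  if (polyorder < 4) stop("`polyorder` must be >= 4 for a fourth derivative")
  if (window <= polyorder) stop("`window` must exceed `polyorder`")
  nb <- length(cube$wavelengths)
  if (nb < window) stop("cube has fewer bands (", nb, ") than `window`")
  step <- diff(cube$wavelengths)
  if (diff(range(step)) > 1e-6 * mean(step)) {
    stop("wavelength grid must be uniform for Savitzky-Golay filtering")
  }
  h <- (window - 1L) / 2L
  coef <- signal::sgolay(p = polyorder, n = window, m = 4, ts = mean(step))
  cc <- coef[h + 1L, ]  # interior (central) filter row

  d <- dim(cube$data)
  flat <- matrix(cube$data, nrow = nb)          # bands x pixels
  out <- matrix(NA_real_, nrow = nb, ncol = ncol(flat))
  interior <- seq(h + 1L, nb - h)
  acc <- matrix(0, nrow = length(interior), ncol = ncol(flat))
  for (k in seq_len(window)) {
    acc <- acc + cc[k] * flat[interior + (k - 1L - h), , drop = FALSE]
  }
  out[interior, ] <- acc
  res <- spectral_cube(cube$wavelengths, array(out, d), kind = "derivative")
  attr(res, "deriv_order") <- 4L
  attr(res, "window") <- window
  attr(res, "polyorder") <- polyorder
  res
}

#' Pigment band amplitude map
#'
#' Pools the fourth-derivative signal over a pigment absorption band into a
#' per-pixel attenuation amplitude. An absorption dip in reflectance has a
#' negative fourth-derivative extremum at its centre, so the amplitude is
#' taken as the maximum of the *negated* fourth derivative within the band,
#' floored at zero: absorption then maps to a positive amplitude that is
#' maximal at the band centre and zero where the spectrum is smooth.
#'
#' @param deriv Derivative cube from [spectral_fourth_derivative()].
#' @param band A [band_window()]; endpoints are snapped to sampled
#'   wavelengths, inclusive.
#' @param statistic `"max"` (default; robust to band-edge snapping on coarse
#'   grids) or `"mean"` over the band.
#' @return A `scalar_image` of nonnegative band amplitudes
#'   (units `"deriv_amplitude"`).
#' @export
band_amplitude_map <- function(deriv, band, statistic = c("max", "mean")) {
  stopifnot(inherits(deriv, "spectral_cube"), inherits(band, "band_window"))
  statistic <- match.arg(statistic)
  if (is.null(attr(deriv, "deriv_order")) || attr(deriv, "deriv_order") != 4L) {
    stop("`deriv` must be produced by spectral_fourth_derivative()")
  }
  idx <- band_indices(deriv$wavelengths, band)
  seg <- -deriv$data[idx, , , drop = FALSE]   # absorption-positive
  f <- if (statistic == "max") {
    function(v) if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE)
  } else {
    function(v) if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }
  amp <- apply(seg, c(2, 3), f)
  scalar_image(pmax(amp, 0), units = "deriv_amplitude")
}

#' Rescale an amplitude map to relative abundance in [0, 1]
#'
#' Linear rescale of `[0, P]` to `[0, 1]`, where `P` is the `clip_pct`
#' percentile of the unmasked values (default 99.5, guarding against hot
#' pixels); values above `P` are set to 1. An all-zero map stays all zero.
#'
#' @param map Nonnegative `scalar_image`.
#' @param clip_pct Upper percentile used as the scaling ceiling.
#' @return A `scalar_image` with `units = "relative_0_1"`.
#' @export
normalize_abundance <- function(map, clip_pct = 99.5) {
  stopifnot(inherits(map, "scalar_image"))
  v <- map$data
  if (any(v < 0, na.rm = TRUE)) stop("map must be nonnegative")
  p <- stats::quantile(v, probs = clip_pct / 100, na.rm = TRUE, names = FALSE)
  out <- if (!is.finite(p) || p <= 0) {
    v * 0
  } else {
    pmin(v / p, 1)
  }
  scalar_image(out, units = "relative_0_1")
}

#' False-colour pigment overlay
#'
#' Paints pixels whose chlorophyll a amplitude exceeds `chla_thresh` green
#' and pixels whose chlorophyll f amplitude exceeds `chlf_thresh` red on top
#' of a structural RGB image. Where both exceed their thresholds the
#' chlorophyll f class wins (red): far-red hotspots are the features of
#' interest inside a chlorophyll-a-rich matrix. With
#' `mode = "continuous"`, the chlorophyll f map (rescaled to `[0, 1]`)
#' is alpha-blended into the red channel instead of a hard classification.
#'
#' @param rgb Structural `rgb_frame` (e.g. from [rgb_composite()]).
#' @param chla,chlf `scalar_image` amplitude maps, co-registered with `rgb`.
#' @param chla_thresh,chlf_thresh Classification thresholds (same units as
#'   the maps).
#' @param mode `"threshold"` (default) or `"continuous"`.
#' @return An `rgb_frame`.
#' @export
pigment_overlay <- function(rgb, chla, chlf, chla_thresh, chlf_thresh,
                            mode = c("threshold", "continuous")) {
  stopifnot(inherits(rgb, "rgb_frame"),
            inherits(chla, "scalar_image"), inherits(chlf, "scalar_image"))
  mode <- match.arg(mode)
  if (!identical(dim(rgb$red), dim(chla$data)) ||
      !identical(dim(rgb$red), dim(chlf$data))) {
    stop("overlay inputs are not co-registered (shape mismatch)")
  }
  r <- rgb$red; g <- rgb$green; b <- rgb$blue
  if (mode == "threshold") {
    sel_a <- !is.na(chla$data) & chla$data > chla_thresh
    sel_f <- !is.na(chlf$data) & chlf$data > chlf_thresh
    sel_a <- sel_a & !sel_f                       # chlorophyll f precedence
    r[sel_a] <- 0; g[sel_a] <- 1; b[sel_a] <- 0
    r[sel_f] <- 1; g[sel_f] <- 0; b[sel_f] <- 0
  } else {
    w <- normalize_abundance(chlf)$data
    w[is.na(w)] <- 0
    r <- (1 - w) * r + w
    g <- (1 - w) * g
    b <- (1 - w) * b
  }
  rgb_frame(r, g, b, t = rgb$t, light = rgb$light)
}

#' Mean and SD spectrum over a region of interest
#'
#' @param cube A `spectral_cube`.
#' @param roi Logical matrix of the cube's image dimension; `TRUE` marks ROI
#'   pixels. Must select at least one pixel.
#' @return A data frame with columns `wavelength`, `mean`, `sd` (population
#'   SD over ROI pixels, so a single-pixel ROI has `sd = 0`) and `n`.
#' @export
extract_roi_spectrum <- function(cube, roi) {
  stopifnot(inherits(cube, "spectral_cube"), is.logical(roi))
  if (!identical(dim(roi), dim(cube$data)[2:3])) {
    stop("roi mask shape does not match cube image dimensions")
  }
  n <- sum(roi, na.rm = TRUE)
  if (n < 1L) stop("empty ROI")
  flat <- matrix(cube$data, nrow = dim(cube$data)[1])
  sel <- flat[, as.vector(roi), drop = FALSE]
  mu <- rowMeans(sel, na.rm = TRUE)
  sdv <- sqrt(rowMeans(sel^2, na.rm = TRUE) - mu^2)
  sdv[sdv < 0 | is.nan(sdv)] <- 0
  data.frame(wavelength = cube$wavelengths, mean = mu, sd = sdv, n = n)
}

#' False-colour emission band map from a fluorescence cube
#'
#' Averages fluorescence intensity within each emission band and assigns the
#' result to a colour channel (the confocal convention here: phycobiliprotein
#' emission 650-660 nm, chlorophyll a 690-700 nm, chlorophyll f 740-750 nm).
#' Channels are independently normalised to their maxima.
#'
#' @param fluor `spectral_cube` with `kind = "fluorescence"`.
#' @param bands Named list mapping channel (`"red"`, `"green"`, `"blue"`) to
#'   a [band_window()]. Bands may overlap; bands outside the sampled range
#'   are an error.
#' @return An `rgb_frame`; channels without an assigned band are zero.
#' @export
emission_band_map <- function(fluor, bands) {
  stopifnot(inherits(fluor, "spectral_cube"))
  if (fluor$kind != "fluorescence") {
    stop("emission_band_map expects a fluorescence cube")
  }
  if (is.null(names(bands)) || !all(names(bands) %in% c("red", "green", "blue"))) {
    stop("`bands` must be a named list with names among red, green, blue")
  }
  zero <- matrix(0, dim(fluor$data)[2], dim(fluor$data)[3])
  chan <- list(red = zero, green = zero, blue = zero)
  for (nm in names(bands)) {
    idx <- band_indices(fluor$wavelengths, bands[[nm]])
    m <- apply(fluor$data[idx, , , drop = FALSE], c(2, 3), mean, na.rm = TRUE)
    mx <- max(m, na.rm = TRUE)
    chan[[nm]] <- if (is.finite(mx) && mx > 0) m / mx else m * 0
  }
  rgb_frame(chan$red, chan$green, chan$blue)
}
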