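# End-to-end convenience wrappers over the stage functions.

#' Run the full pigment-mapping pipeline
#'
#' Dark-corrects the raw and standard stacks, converts to % reflectance,
#' computes the fourth derivative, and pools it into chlorophyll a and
#' chlorophyll f band-amplitude maps plus the 0--1 relative chlorophyll f
#' abundance map and a structural RGB composite.
#'
#' @param raw,dark,standard Raw `spectral_cube`s (specimen, dark frame,
#'   reflectance standard).
#' @param standard_pct Nominal standard reflectance in % (default 20).
#' @param chla_band,chlf_band [band_window()]s (defaults 670--680 and
#'   718--722 nm).
#' @param window,polyorder Savitzky-Golay settings; the defaults (9, 5) suit
#'   clean spectra, wider windows (e.g. 31) suppress band noise in noisy
#'   cubes.
#' @param statistic Band pooling statistic, see [band_amplitude_map()].
#' @return List with `reflectance`, `deriv`, `rgb`, `chla`, `chlf`,
#'   `chlf_rel`.
#' @export
pigment_pipeline <- function(raw, dark, standard, standard_pct = 20,
                             chla_band = band_window(670, 680),
                             chlf_band = band_window(718, 722),
                             window = 9, polyorder = 5,
                             statistic = "max") {
  sample_dc <- dark_correct(raw, dark)
  standard_dc <- dark_correct(standard, dark)
  refl <- to_reflectance(sample_dc, standard_dc, standard_pct)
  deriv <- spectral_fourth_derivative(refl, window = window,
                                      polyorder = polyorder)
  chla <- band_amplitude_map(deriv, chla_band, statistic = statistic)
  chlf <- band_amplitude_map(deriv, chlf_band, statistic = statistic)
  list(reflectance = refl, deriv = deriv, rgb = rgb_composite(refl),
       chla = chla, chlf = chlf, chlf_rel = normalize_abundance(chlf))
}

#' Convert an optode frame series to a calibrated O2 series
#'
#' Computes ratio images, references them to the dark-anoxic state, inverts
#' the calibration, and bundles the result with the light events.
#'
#' @param frames List of [rgb_frame()] objects.
#' @param model An `o2_calibration`.
#' @param events Data frame (`t_min`, `event`) of light switches.
#' @param min_dark_minutes Dark-reference rule, see [dark_reference()].
#' @param smooth Odd box-filter size applied to each delta-ratio image
#'   before inversion (1 = off); see [box_filter()].
#' @param bias_correct If `TRUE` (default), estimate the channel noise from
#'   the replicate dark-reference frames and apply the convexity
#'   (delta-method) bias correction of [invert_calibration()], which
#'   counteracts the noise-driven overestimation of O2 near the calibration
#'   asymptote. Skipped automatically when fewer than two reference frames
#'   are available.
#' @param ... Passed to [ratio_image()].
#' @return An [o2_series()].
#' @export
o2_image_series <- function(frames, model, events, min_dark_minutes = 45,
                            smooth = 1, bias_correct = TRUE, ...) {
  rdk <- dark_reference(frames, min_dark_minutes = min_dark_minutes, ...)
  n_ref <- attr(rdk, "n_frames")
  noise_var <- NULL
  if (bias_correct && n_ref >= 2L) {
    is_ref <- vapply(frames, function(f) {
      identical(f$light, "dark") && is.finite(f$t) && f$t >= min_dark_minutes
    }, logical(1))
    sigma_c <- estimate_channel_noise(frames[is_ref])
    green_level <- mean(vapply(frames[is_ref],
                               function(f) mean(f$green), numeric(1)))
    if (sigma_c > 0 && green_level > 0) {
      noise_var <- function(r) {
        delta_ratio_noise_var(r, rdk, sigma_c, green_level, n_ref)
      }
    }
  }
  o2 <- lapply(frames, function(f) {
    r <- ratio_image(f, ...)
    dr <- delta_ratio(r, rdk)
    if (smooth > 1) dr <- box_filter(dr, smooth)
    invert_calibration(model, dr,
                       noise_var = if (is.null(noise_var)) NULL
                                   else noise_var(r))
  })
  o2_series(o2, events)
}
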