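#' Red/green ratio image of an optode frame
#'
#' The O2-sensitive red indicator emission is referenced to the constant
#' green reference-dye emission by a pixelwise quotient R = red/green.
#' Pixels whose green signal falls below `green_floor` carry no usable
#' reference and are masked (`NA`); the blue channel is ignored.
#'
#' @param frame An [rgb_frame()].
#' @param green_floor Minimum usable green level, in channel counts. The
#'   default is 1% of `dynamic_range`.
#' @param dynamic_range Full scale of the channel data (1 for normalised
#'   `[0, 1]` frames, 255 or 65535 for integer counts).
#' @return A `scalar_image` with `units = "ratio"`; `t` and `light` of the
#'   source frame are carried in attributes.
#' @export
ratio_image <- function(frame, green_floor = NULL, dynamic_range = 1) {
  stopifnot(inherits(frame, "rgb_frame"))
  if (is.null(green_floor)) green_floor <- 0.01 * dynamic_range
  r <- frame$red / frame$green
  r[!is.finite(r) | frame$green < green_floor] <- NA_real_
  out <- scalar_image(r, units = "ratio")
  attr(out, "t") <- frame$t
  attr(out, "light") <- frame$light
  out
}

#' Reference a ratio image to the dark-anoxic state
#'
#' Computes the delta ratio `dR = R_dark - R` per pixel, where `R_dark` is a
#' ratio image recorded at the dark, anoxic steady state. Referencing removes
#' static background (e.g. chlorophyll a fluorescence bleeding into the red
#' channel) and anchors the calibration at `dR(0) = 0`. Masks are the union
#' of the input masks (masks only ever grow along the pipeline).
#'
#' @param r Ratio `scalar_image` of the frame of interest.
#' @param r_dark Ratio `scalar_image` of the dark-anoxic reference.
#' @return A `scalar_image` with `units = "delta_ratio"`.
#' @export
delta_ratio <- function(r, r_dark) {
  stopifnot(inherits(r, "scalar_image"), inherits(r_dark, "scalar_image"))
  if (!identical(dim(r$data), dim(r_dark$data))) {
    stop("ratio images are not co-registered (shape mismatch)")
  }
  out <- scalar_image(r_dark$data - r$data, units = "delta_ratio")
  attr(out, "t") <- attr(r, "t")
  attr(out, "light") <- attr(r, "light")
  attr(out, "reference_t") <- attr(r_dark, "t")
  out
}

#' Dark-anoxic reference ratio image from a frame series
#'
#' Default reference rule: the mean ratio image of all frames labelled
#' `dark` with `t >= min_dark_minutes` (default 45 min), i.e. frames
#' recorded after the system has relaxed to dark-anoxic steady state.
#'
#' @param frames List of [rgb_frame()] objects.
#' @param min_dark_minutes Earliest dark time included in the reference.
#' @param ... Passed to [ratio_image()].
#' @return A ratio `scalar_image` (mean over the qualifying frames).
#' @export
dark_reference <- function(frames, min_dark_minutes = 45, ...) {
  sel <- vapply(frames, function(f) {
    identical(f$light, "dark") && is.finite(f$t) && f$t >= min_dark_minutes
  }, logical(1))
  if (!any(sel)) {
    stop("no dark frames with t >= ", min_dark_minutes,
         " min available for the anoxic reference")
  }
  ratios <- lapply(frames[sel], ratio_image, ...)
  acc <- Reduce(`+`, lapply(ratios, function(x) x$data))
  out <- scalar_image(acc / sum(sel), units = "ratio")
  attr(out, "t") <- max(vapply(frames[sel], function(f) f$t, numeric(1)))
  attr(out, "n_frames") <- sum(sel)
  out
}

#' Fit the exponential delta-ratio calibration
#'
#' Fits the saturating single-exponential calibration
#' `dR(C) = a * (1 - exp(-b * C))` to ROI-mean delta-ratio values recorded at
#' a series of known O2 levels (% air saturation). This is the simplest model
#' consistent with an exponentially decaying ratio `R(C) = R_inf + a *
#' exp(-b * C)` and with `dR(0) = 0` at the anoxic reference. Fitting is by
#' Levenberg-Marquardt nonlinear least squares, initialised at
#' `a0 = max(dR)` and `b0` solved from the highest-O2 point.
#'
#' @param pairs Data frame with columns `delta_r` and `o2_percent` (% air
#'   saturation). At least 3 points over at least 2 distinct O2 levels are
#'   required, and the series should include (near-)anoxia.
#' @return An object of class `o2_calibration`: list with `a`, `b`, `rss`,
#'   `n` and the underlying `nls` fit.
#' @export
fit_calibration <- function(pairs) {
  stopifnot(is.data.frame(pairs),
            all(c("delta_r", "o2_percent") %in% names(pairs)))
  pairs <- pairs[is.finite(pairs$delta_r) & is.finite(pairs$o2_percent), ]
  if (nrow(pairs) < 3L) stop("calibration needs >= 3 points")
  if (length(unique(pairs$o2_percent)) < 2L) {
    stop("calibration needs >= 2 distinct O2 levels")
  }
  if (min(pairs$o2_percent) > 5) {
    warning("calibration series does not reach (near-)anoxia; ",
            "the dR(0) = 0 anchor is extrapolated")
  }
  a0 <- max(pairs$delta_r)
  if (a0 <= 0) stop("calibration fit failed: all delta_r <= 0")
  hi <- which.max(pairs$o2_percent)
  frac <- min(pairs$delta_r[hi] / (a0 * 1.05), 1 - 1e-3)
  b0 <- if (frac > 0) -log(1 - frac) / pairs$o2_percent[hi] else 0.01
  fit <- tryCatch(
    minpack.lm::nlsLM(delta_r ~ a * (1 - exp(-b * o2_percent)),
                      data = pairs, start = list(a = a0 * 1.05, b = b0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("calibration fit did not converge: ",
                             conditionMessage(e)))
  cf <- stats::coef(fit)
  if (cf[["a"]] <= 0 || cf[["b"]] <= 0) {
    stop(sprintf("calibration fit unphysical: a = %.4g, b = %.4g",
                 cf[["a"]], cf[["b"]]))
  }
  structure(list(a = unname(cf[["a"]]), b = unname(cf[["b"]]),
                 rss = sum(stats::residuals(fit)^2), n = nrow(pairs),
                 fit = fit),
            class = "o2_calibration")
}

#' @export
print.o2_calibration <- function(x, ...) {
  cat(sprintf(
    "<o2_calibration> dR(C) = a(1 - exp(-bC)); a = %.4g, b = %.4g per %% airsat; rss = %.3g (n = %d)\n",
    x$a, x$b, x$rss, x$n))
  invisible(x)
}

#' Predict delta-ratio from the calibration model
#'
#' @param object An `o2_calibration`.
#' @param o2_percent O2 in % air saturation.
#' @param ... Unused.
#' @return Numeric vector of delta-ratio values.
#' @export
predict.o2_calibration <- function(object, o2_percent, ...) {
  object$a * (1 - exp(-object$b * o2_percent))
}

#' Invert the calibration: delta-ratio image to O2 image
#'
#' Applies `C = -log(1 - dR/a) / b` per pixel. Delta ratios are clamped to
#' `[0, a (1 - eps)]` before inversion so the logarithm stays finite near the
#' asymptote; clamped pixels are flagged. Recovered O2 is capped at
#' `cap_percent` (% air saturation).
#'
#' Because the inversion is convex in the delta ratio, zero-mean noise on
#' `dR` inflates the expected O2 reading, increasingly so toward the
#' asymptote. If the pixelwise delta-ratio noise variance is supplied via
#' `noise_var`, the second-order (delta-method) correction
#' `-0.5 * noise_var / (b (a - dR)^2)` is applied where the expansion is
#' valid (`a - dR > 3 sd`); the corrected value is floored at 0.
#'
#' @param model An `o2_calibration`.
#' @param dr Delta-ratio `scalar_image`.
#' @param eps Clamp margin below the asymptote (default 1e-6).
#' @param cap_percent Upper cap on recovered O2 (default 150% air sat).
#' @param noise_var Optional variance of the delta-ratio noise (scalar or
#'   matrix) for the convexity bias correction.
#' @return An object of class `o2_image`: list with `data` (% air
#'   saturation), `t`, `light`, and logical matrices `clamped` (delta ratio
#'   outside `[0, a(1-eps)]`) and `saturated` (above the asymptote only --
#'   these pixels carry no usable O2 reading).
#' @export
invert_calibration <- function(model, dr, eps = 1e-6, cap_percent = 150,
                               noise_var = NULL) {
  stopifnot(inherits(model, "o2_calibration"), inherits(dr, "scalar_image"))
  v <- dr$data
  hi <- model$a * (1 - eps)
  saturated <- !is.na(v) & v > hi     # beyond the asymptote: no O2 reading
  clamped <- saturated | (!is.na(v) & v < 0)
  v <- pmin(pmax(v, 0), hi)
  o2 <- -log(1 - v / model$a) / model$b
  if (!is.null(noise_var)) {
    # second-order correction, applied only where the expansion is valid
    # (well away from the asymptote); elsewhere the raw inversion stands
    valid <- (model$a - v) > 3 * sqrt(noise_var)
    corr <- pmax(o2 - 0.5 * noise_var / (model$b * (model$a - v)^2), 0)
    o2 <- ifelse(!is.na(v) & valid, corr, o2)
  }
  o2 <- pmin(o2, cap_percent)
  structure(list(data = o2, t = attr(dr, "t"), light = attr(dr, "light"),
                 clamped = clamped, saturated = saturated),
            class = "o2_image")
}

#' Estimate per-channel camera noise from replicate dark frames
#'
#' Pools the pixelwise temporal standard deviation of the red and green
#' channels over replicate frames of the same (steady) state, giving a
#' single channel noise SD in counts. Used to propagate noise into the
#' delta-ratio for the convexity bias correction of [invert_calibration()].
#'
#' @param frames List of at least two [rgb_frame()] objects imaging the
#'   same steady state.
#' @return Scalar channel noise SD.
#' @export
estimate_channel_noise <- function(frames) {
  if (length(frames) < 2L) stop("need >= 2 replicate frames")
  stack_sd <- function(chan) {
    arrs <- lapply(frames, function(f) f[[chan]])
    mu <- Reduce(`+`, arrs) / length(arrs)
    ss <- Reduce(`+`, lapply(arrs, function(m) (m - mu)^2))
    sqrt(mean(ss / (length(arrs) - 1)))
  }
  mean(c(stack_sd("red"), stack_sd("green")))
}

# pixelwise delta-ratio noise variance under additive channel noise:
# Var(R) ~ sigma_c^2 (1 + R^2) / green^2, plus the (averaged) reference term
delta_ratio_noise_var <- function(r, r_dark, sigma_c, green_level, n_ref) {
  vr <- sigma_c^2 * (1 + r$data^2) / green_level^2
  vref <- sigma_c^2 * (1 + r_dark$data^2) / (green_level^2 * n_ref)
  vr + vref
}

#' @export
print.o2_image <- function(x, ...) {
  rng <- range(x$data, na.rm = TRUE)
  cat(sprintf(
    "<o2_image> %d x %d, t = %s min, light = %s, %.1f-%.1f %% airsat, %d clamped\n",
    nrow(x$data), ncol(x$data), format(x$t),
    ifelse(is.na(x$light), "NA", x$light), rng[1], rng[2], sum(x$clamped)))
  invisible(x)
}
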