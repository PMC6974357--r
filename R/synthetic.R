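# Synthetic scenes with closed-form ground truth.
#
# The generators emulate the two imaging experiments: (i) a hyperspectral
# reflectance cube of a rock cross-section with a chlorophyll-a-rich surface
# biofilm layer and deeper, patchy chlorophyll f hotspots, and (ii) a
# ratiometric O2-optode RGB time series in which hotspot O2 relaxes
# exponentially toward a light-dependent steady state after each light
# switch. O2 dynamics are pixel-local (no lateral diffusion) so that every
# stage of the analysis has an analytic oracle.

#' Sum-of-Gaussian-blobs amplitude field
#'
#' @param nrow,ncol Field dimensions in pixels.
#' @param centers Data frame with columns `row`, `col` and `amplitude`.
#' @param radius Gaussian radius (SD) of each blob in pixels.
#' @return Matrix in `[0, 1]` (capped at 1).
#' @export
hotspot_field <- function(nrow, ncol, centers, radius) {
  A <- matrix(0, nrow, ncol)
  rr <- row(A); cc <- col(A)
  for (k in seq_len(nrow(centers))) {
    d2 <- (rr - centers$row[k])^2 + (cc - centers$col[k])^2
    A <- A + centers$amplitude[k] * exp(-d2 / (2 * radius^2))
  }
  pmin(A, 1)
}

# smooth horizontal surface-layer field: ~1 in the top `depth_rows` rows,
# rolling off over `edge` rows
layer_field <- function(nrow, ncol, depth_rows, edge = 2) {
  prof <- 1 / (1 + exp((seq_len(nrow) - depth_rows) / edge))
  matrix(prof, nrow, ncol)
}

#' Parameters of a synthetic hyperspectral scene
#'
#' Defaults emulate the study system: a 400--800 nm reflectance cube at 2 nm
#' resolution over a 48 x 48 pixel cross-section, with a chlorophyll a
#' absorption dip (675 nm, sigma 6 nm, max depth 0.4) in a ~10-pixel surface
#' layer and a chlorophyll f dip (720 nm, sigma 10 nm, max depth 0.5) in
#' three deeper endolithic hotspots. The smooth baseline is a cubic in
#' wavelength; the imaging chain uses a 20% reflectance standard and a
#' constant dark offset.
#'
#' @param nrow,ncol Image size in pixels.
#' @param wavelengths Uniform wavelength grid (nm).
#' @param baseline_coef Cubic baseline coefficients in `u = (lambda - 600) /
#'   200`, as reflectance fraction.
#' @param chla_center,chla_sigma,chla_depth Chlorophyll a dip: centre (nm),
#'   Gaussian sigma (nm), maximum fractional depth.
#' @param chlf_center,chlf_sigma,chlf_depth Chlorophyll f dip, same meaning.
#' @param chla_layer_rows Thickness of the surface biofilm layer in rows.
#' @param n_hotspots Number of chlorophyll f hotspots (ignored when
#'   `chlf_centers` is given).
#' @param hotspot_radius Hotspot Gaussian radius in pixels.
#' @param chlf_centers Optional data frame (`row`, `col`, `amplitude`)
#'   fixing the hotspot layout; drawn at random in the endolithic zone
#'   (below the surface layer) when `NULL`.
#' @param standard_counts Peak counts of the reflectance-standard spectrum.
#' @param dark_counts Dark offset in counts.
#' @param standard_pct Nominal reflectance of the standard (%).
#' @param noise_sigma Additive Gaussian noise, expressed in % reflectance
#'   equivalent (0 = noiseless).
#' @param seed RNG seed (mandatory; generators are reproducible bit for bit).
#' @return A list of class `scene_params`.
#' @export
scene_params <- function(nrow = 48, ncol = 48,
                         wavelengths = seq(400, 800, by = 2),
                         baseline_coef = c(0.40, 0.05, -0.02, 0.01),
                         chla_center = 675, chla_sigma = 6, chla_depth = 0.4,
                         chlf_center = 720, chlf_sigma = 10, chlf_depth = 0.5,
                         chla_layer_rows = 10,
                         n_hotspots = 3, hotspot_radius = 4,
                         chlf_centers = NULL,
                         standard_counts = 2000, dark_counts = 100,
                         standard_pct = 20, noise_sigma = 0, seed) {
  if (missing(seed)) stop("scene_params requires an explicit `seed`")
  stopifnot(chla_depth >= 0, chla_depth < 1, chlf_depth >= 0, chlf_depth < 1)
  if (chla_center < min(wavelengths) || chla_center > max(wavelengths) ||
      chlf_center < min(wavelengths) || chlf_center > max(wavelengths)) {
    stop("dip centres must lie within the wavelength grid")
  }
  structure(as.list(environment()), class = "scene_params")
}

gaussian_dip <- function(lambda, center, sigma) {
  exp(-(lambda - center)^2 / (2 * sigma^2))
}

#' Generate a synthetic hyperspectral scene with known truth
#'
#' Forward model: `reflectance(lambda, x, y) = 100 * B(lambda) *
#' (1 - Aa(x, y) Ga(lambda)) * (1 - Af(x, y) Gf(lambda))` with Gaussian dip
#' profiles `G` and spatial amplitude fields `A`. The raw cube is the
#' reflectance re-expressed through the imaging chain
#' (`raw = reflectance / standard_pct * standard_ref + dark + noise`), so
#' running [dark_correct()] and [to_reflectance()] recovers the truth
#' exactly in the noiseless case.
#'
#' @param p A [scene_params()] object.
#' @return List with `raw`, `dark`, `standard` (`spectral_cube`s) and
#'   `truth`: list with `reflectance` cube, matrices `chla_map`, `chlf_map`
#'   (the per-pixel dip depths) and the hotspot `centers`.
#' @export
synth_hyperspectral_scene <- function(p) {
  stopifnot(inherits(p, "scene_params"))
  with_seed(p$seed, {
    if (is.null(p$chlf_centers)) {
      lo <- p$chla_layer_rows + ceiling(2 * p$hotspot_radius)
      hi <- p$nrow - ceiling(2 * p$hotspot_radius)
      if (lo >= hi) stop("image too small for endolithic hotspots")
      p$chlf_centers <- data.frame(
        row = sample(seq(lo, hi), p$n_hotspots, replace = TRUE),
        col = sample(seq(1 + ceiling(2 * p$hotspot_radius),
                         p$ncol - ceiling(2 * p$hotspot_radius)),
                     p$n_hotspots, replace = TRUE),
        amplitude = 1)
    }
    A_a <- layer_field(p$nrow, p$ncol, p$chla_layer_rows) * p$chla_depth
    A_f <- hotspot_field(p$nrow, p$ncol, p$chlf_centers, p$hotspot_radius) *
      p$chlf_depth

    u <- (p$wavelengths - 600) / 200
    B <- p$baseline_coef[1] + p$baseline_coef[2] * u +
      p$baseline_coef[3] * u^2 + p$baseline_coef[4] * u^3
    G_a <- gaussian_dip(p$wavelengths, p$chla_center, p$chla_sigma)
    G_f <- gaussian_dip(p$wavelengths, p$chlf_center, p$chlf_sigma)

    nb <- length(p$wavelengths)
    npix <- p$nrow * p$ncol
    # bands x pixels: outer products of spectral and spatial factors
    refl <- (100 * B) * (1 - outer(G_a, as.vector(A_a))) *
      (1 - outer(G_f, as.vector(A_f)))
    std_ref <- p$standard_counts *
      (0.7 + 0.3 * (p$wavelengths - min(p$wavelengths)) /
         diff(range(p$wavelengths)))
    sigma_counts <- p$noise_sigma * std_ref / p$standard_pct  # per band

    raw <- refl / p$standard_pct * std_ref + p$dark_counts
    std <- matrix(std_ref, nb, npix) + p$dark_counts
    if (p$noise_sigma > 0) {
      raw <- raw + matrix(stats::rnorm(nb * npix), nb) * sigma_counts
      std <- std + matrix(stats::rnorm(nb * npix), nb) * sigma_counts
      raw <- pmax(raw, 0); std <- pmax(std, 0)
    }
    dims <- c(nb, p$nrow, p$ncol)
    list(
      raw = spectral_cube(p$wavelengths, array(raw, dims), "raw"),
      dark = spectral_cube(p$wavelengths,
                           array(p$dark_counts, dims), "raw"),
      standard = spectral_cube(p$wavelengths, array(std, dims), "raw"),
      truth = list(
        reflectance = spectral_cube(p$wavelengths, array(refl, dims),
                                    "reflectance"),
        chla_map = A_a, chlf_map = A_f, centers = p$chlf_centers,
        params = p))
  })
}

#' Parameters of a synthetic optode time series
#'
#' Defaults emulate the O2-imaging experiment: frames every 5 min over
#' 0--75 min; the series starts at the NIR-driven steady state, the light is
#' switched off at 5 min (O2 decays to anoxia) and on again at 55 min (O2
#' rises back). Per-pixel O2 relaxes exponentially with time constant
#' `tau_min` (5 min: near-steady within 15--20 min of switching, dissipating
#' within minutes of darkening). Steady-state O2 peaks at `c_max` (60 % air
#' saturation) in hotspots. The red indicator channel follows `red = green *
#' (r_inf + a exp(-b C))` over a constant green reference, giving the
#' delta-ratio calibration `dR(C) = a (1 - exp(-b C))` with defaults
#' `a = 0.8`, `b = 0.05` per % air saturation.
#'
#' @param nrow,ncol Image size in pixels.
#' @param a,b True calibration parameters.
#' @param r_inf Residual red/green ratio at full quenching.
#' @param green_level Constant green channel level (normalised counts).
#' @param c_max Peak steady-state O2 in hotspots (% air saturation).
#' @param centers Optional hotspot layout data frame (`row`, `col`,
#'   `amplitude`); drawn at random when `NULL`.
#' @param n_hotspots,hotspot_radius Hotspot layout when `centers` is `NULL`.
#' @param tau_min Relaxation time constant (minutes).
#' @param times Frame times (minutes), strictly increasing.
#' @param events Data frame (`t_min`, `event`) of light switches; the series
#'   starts with the light on.
#' @param snr Signal-to-noise ratio of the green channel
#'   (`noise sd = green_level / snr`); `Inf` for noiseless frames.
#' @param temp_c,salinity Water conditions used for truth rates in
#'   volumetric units.
#' @param seed RNG seed (mandatory).
#' @return A list of class `optode_params`.
#' @export
optode_params <- function(nrow = 48, ncol = 48, a = 0.8, b = 0.05,
                          r_inf = 0.2, green_level = 0.5, c_max = 60,
                          centers = NULL, n_hotspots = 3, hotspot_radius = 4,
                          tau_min = 5, times = seq(0, 75, by = 5),
                          events = data.frame(
                            t_min = c(5, 55),
                            event = c("light_off", "light_on")),
                          snr = Inf, temp_c = 23, salinity = 35, seed) {
  if (missing(seed)) stop("optode_params requires an explicit `seed`")
  stopifnot(a > 0, b > 0, tau_min > 0, c_max >= 0, green_level > 0,
            all(diff(times) > 0))
  structure(as.list(environment()), class = "optode_params")
}

# light state just before/at time t, given events and an initially-on light
light_state_at <- function(t, events) {
  prior <- events[events$t_min < t, , drop = FALSE]
  if (nrow(prior) == 0L) return("nir_on")
  if (prior$event[which.max(prior$t_min)] == "light_on") "nir_on" else "dark"
}

# closed-form O2 field at time t: piecewise exponential relaxation toward
# C_ss (light on) or 0 (dark), starting from the light-on steady state
o2_field_at <- function(t, c_ss, events, tau) {
  ev <- events[order(events$t_min), , drop = FALSE]
  state <- c_ss           # steady light before the first event
  t0 <- -Inf
  target <- c_ss
  for (k in seq_len(nrow(ev))) {
    if (ev$t_min[k] >= t) break
    # advance to the event time, then switch target
    state <- if (is.infinite(t0)) state else
      target + (state - target) * exp(-(ev$t_min[k] - t0) / tau)
    t0 <- ev$t_min[k]
    target <- if (ev$event[k] == "light_on") c_ss else c_ss * 0
  }
  if (is.infinite(t0)) return(state)
  target + (state - target) * exp(-(t - t0) / tau)
}

#' Generate a synthetic optode RGB time series with known truth
#'
#' @param p An [optode_params()] object.
#' @return List with `frames` (list of [rgb_frame()]), `manifest` (data
#'   frame `t_minutes`, `light_state`) and `truth`: the steady-state field
#'   `c_ss`, per-frame O2 fields `c_fields` (% air saturation), and for each
#'   event both the instantaneous initial rate and the bracket-averaged rate
#'   over the adjacent frame interval, in % air saturation per min and in
#'   umol O2 L^-1 min^-1.
#' @export
synth_optode_timeseries <- function(p) {
  stopifnot(inherits(p, "optode_params"))
  with_seed(p$seed, {
    if (is.null(p$centers)) {
      m <- ceiling(2 * p$hotspot_radius)
      p$centers <- data.frame(
        row = sample(seq(1 + m, p$nrow - m), p$n_hotspots, replace = TRUE),
        col = sample(seq(1 + m, p$ncol - m), p$n_hotspots, replace = TRUE),
        amplitude = 1)
    }
    c_ss <- hotspot_field(p$nrow, p$ncol, p$centers, p$hotspot_radius) * p$c_max

    c_fields <- lapply(p$times, o2_field_at, c_ss = c_ss,
                       events = p$events, tau = p$tau_min)
    noise_sd <- if (is.finite(p$snr)) p$green_level / p$snr else 0
    frames <- vector("list", length(p$times))
    for (i in seq_along(p$times)) {
      ratio <- p$r_inf + p$a * exp(-p$b * c_fields[[i]])
      red <- p$green_level * ratio
      green <- matrix(p$green_level, p$nrow, p$ncol)
      blue <- matrix(0.02, p$nrow, p$ncol)
      if (noise_sd > 0) {
        red <- pmax(red + matrix(stats::rnorm(length(red), sd = noise_sd),
                                 p$nrow), 0)
        green <- pmax(green + matrix(stats::rnorm(length(green), sd = noise_sd),
                                     p$nrow), 0)
      }
      frames[[i]] <- rgb_frame(red, green, blue, t = p$times[i],
                               light = light_state_at(p$times[i], p$events))
    }
    manifest <- data.frame(
      t_minutes = p$times,
      light_state = vapply(p$times, light_state_at, character(1),
                           events = p$events))

    conv <- airsat_to_concentration(1, p$temp_c, p$salinity)  # umol/L per %airsat
    event_truth <- lapply(seq_len(nrow(p$events)), function(k) {
      ev <- p$events$t_min[k]
      ib <- max(which(p$times <= ev)); ia <- min(which(p$times > ev))
      dt <- p$times[ia] - p$times[ib]
      bracket <- (c_fields[[ia]] - c_fields[[ib]]) / dt
      c_ev <- o2_field_at(ev, c_ss, p$events, p$tau_min)
      inst <- if (p$events$event[k] == "light_on") {
        (c_ss - c_ev) / p$tau_min
      } else {
        -c_ev / p$tau_min
      }
      list(event = p$events$event[k], t_min = ev, dt_min = dt,
           bracket_airsat = bracket, bracket_umol = bracket * conv,
           instant_airsat = inst, instant_umol = inst * conv)
    })
    list(frames = frames, manifest = manifest,
         truth = list(c_ss = c_ss, c_fields = c_fields,
                      events = event_truth, centers = p$centers, params = p))
  })
}

#' Generate a synthetic calibration series
#'
#' Delta-ratio values `dR = a (1 - exp(-b C)) + noise` at a series of known
#' O2 levels, as produced by imaging a sensor-coated slide while stepping
#' the water O2 content from air saturation down to anoxia.
#'
#' @param a,b True calibration parameters.
#' @param levels O2 levels in % air saturation (should span 0--100).
#' @param sigma Gaussian noise SD on the delta-ratio values.
#' @param seed RNG seed.
#' @return Data frame with columns `o2_percent` and `delta_r`.
#' @export
synth_calibration_series <- function(a = 0.8, b = 0.05,
                                     levels = c(0, 5, 10, 20, 40, 60, 80, 100),
                                     sigma = 0, seed = 1) {
  with_seed(seed, {
    dr <- a * (1 - exp(-b * levels))
    if (sigma > 0) dr <- dr + stats::rnorm(length(levels), sd = sigma)
    data.frame(o2_percent = levels, delta_r = dr)
  })
}

#' Generate co-located hyperspectral and optode experiments
#'
#' Draws one hotspot layout and uses it for both the chlorophyll f
#' absorption field of the hyperspectral scene and the steady-state O2
#' production field of the optode series, emulating the finding that
#' NIR-driven O2 hotspots overlap regions of high chlorophyll f absorption.
#'
#' @param seed RNG seed.
#' @param nrow,ncol Image size.
#' @param n_hotspots,hotspot_radius Shared hotspot layout.
#' @param noise_sigma Hyperspectral noise (% reflectance).
#' @param snr Optode signal-to-noise ratio.
#' @param ... Further arguments forwarded to both parameter constructors is
#'   not supported; adjust via the returned params instead.
#' @return List with `scene` (from [synth_hyperspectral_scene()]), `optode`
#'   (from [synth_optode_timeseries()]) and the shared `centers`.
#' @export
synth_colocated_experiment <- function(seed, nrow = 48, ncol = 48,
                                       n_hotspots = 3, hotspot_radius = 4,
                                       noise_sigma = 0, snr = Inf, ...) {
  sp0 <- scene_params(nrow = nrow, ncol = ncol, seed = seed)
  centers <- with_seed(seed, {
    m <- ceiling(2 * hotspot_radius)
    lo <- sp0$chla_layer_rows + m
    data.frame(row = sample(seq(lo, nrow - m), n_hotspots, replace = TRUE),
               col = sample(seq(1 + m, ncol - m), n_hotspots, replace = TRUE),
               amplitude = 1)
  })
  sp <- scene_params(nrow = nrow, ncol = ncol, chlf_centers = centers,
                     hotspot_radius = hotspot_radius,
                     noise_sigma = noise_sigma, seed = seed + 1)
  op <- optode_params(nrow = nrow, ncol = ncol, centers = centers,
                      hotspot_radius = hotspot_radius, snr = snr,
                      seed = seed + 2)
  list(scene = synth_hyperspectral_scene(sp),
       optode = synth_optode_timeseries(op),
       centers = centers)
}
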