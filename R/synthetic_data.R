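logistic <- function(x, mid, scale) stats::plogis((x - mid) / scale)
gauss <- function(x, mid, width) exp(-((x - mid) / width)^2)

#' Parameters for the synthetic leaf-spectra generator
#'
#' Band-level targets for the parametric leaf curves. Defaults encode the
#' measured regularities of live foliage: upper surfaces diffusely
#' reflect 1-2% of incident UV (300-400 nm) while transmitting under
#' 0.06% (a reflectance:transmittance ratio above 25), the ratio falls to
#' about 1.5 in the blue (400-500 nm), and reflectance is 0.7-1.3 times
#' transmittance in the green and red (500-700 nm).
#'
#' @param kind `"deciduous"` or `"rainforest"`; rainforest leaves are
#'   modelled slightly darker and less transmissive.
#' @param uv_refl Target UV reflectance level.
#' @param uv_trans Baseline UV transmittance (fraction of incident
#'   light).
#' @param blue_refl,blue_trans Amplitudes of the blue logistic rise of
#'   reflectance and transmittance.
#' @param green_refl,green_trans Amplitudes of the green (chlorophyll
#'   window) Gaussian peak.
#' @param red_edge_refl,red_edge_trans Amplitudes of the red-edge rise
#'   near 700 nm.
#' @param green_peak Position of the green peak, nm.
#' @param lower_brighten Visible-band brightening of the lower surface
#'   relative to the upper (lower leaf surfaces are typically paler in
#'   the visible but equally UV-dark).
#' @param jitter_sd Log-normal relative jitter applied to the amplitudes
#'   when drawing a random leaf (0 = deterministic curve).
#' @return A list of class `lc_leaf_params`.
#' @export
leaf_spectrum_params <- function(kind = c("deciduous", "rainforest"),
                                 uv_refl = NULL, uv_trans = 2e-4,
                                 blue_refl = NULL, blue_trans = NULL,
                                 green_refl = NULL, green_trans = NULL,
                                 red_edge_refl = 0.040,
                                 red_edge_trans = 0.050,
                                 green_peak = 550,
                                 lower_brighten = 0.25,
                                 jitter_sd = 0.05) {
  kind <- match.arg(kind)
  defaults <- if (kind == "deciduous")
    list(uv_refl = 0.015, blue_refl = 0.022, blue_trans = 0.026,
         green_refl = 0.075, green_trans = 0.085)
  else
    list(uv_refl = 0.013, blue_refl = 0.020, blue_trans = 0.022,
         green_refl = 0.060, green_trans = 0.065)
  structure(list(
    kind = kind,
    uv_refl = uv_refl %||% defaults$uv_refl,
    uv_trans = uv_trans,
    blue_refl = blue_refl %||% defaults$blue_refl,
    blue_trans = blue_trans %||% defaults$blue_trans,
    green_refl = green_refl %||% defaults$green_refl,
    green_trans = green_trans %||% defaults$green_trans,
    red_edge_refl = red_edge_refl, red_edge_trans = red_edge_trans,
    green_peak = green_peak, lower_brighten = lower_brighten,
    jitter_sd = jitter_sd), class = "lc_leaf_params")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate leaf optical spectra against the foliage band constraints
#'
#' Checks the band regularities the generator targets (and that measured
#' spectra are expected to satisfy): UV reflectance in \[0.01, 0.02\], UV
#' transmittance below 0.0006 of incident light, UV
#' reflectance:transmittance above 25, and green/red reflectance within
#' 0.7-1.3 times transmittance. Also checks the physical invariants
#' (values in \[0, 1\], `R_u + T <= 1`).
#'
#' @param optics A [leaf_optics()].
#' @param strict If `TRUE`, fail with an error naming the violated
#'   constraint; otherwise return the check table.
#' @return Data.frame of checks (`name`, `value`, `ok`), invisibly when
#'   `strict`.
#' @export
validate_leaf_optics <- function(optics, strict = TRUE) {
  stopifnot(inherits(optics, "lc_leaf_optics"))
  uv_r <- band_mean(optics$R_u, 300, 400)
  uv_t <- band_mean(optics$T_leaf, 300, 400)
  gr_r <- band_mean(optics$R_u, 500, 700)
  gr_t <- band_mean(optics$T_leaf, 500, 700)
  checks <- data.frame(
    name = c("uv_reflectance_in_1_2_percent", "uv_transmittance_below_0.06_percent",
             "uv_refl_trans_ratio_above_25", "green_red_ratio_in_0.7_1.3",
             "energy_conservation"),
    value = c(uv_r, uv_t, uv_r / uv_t, gr_r / gr_t,
              max(optics$R_u$value + optics$T_leaf$value)),
    ok = c(uv_r >= 0.01 & uv_r <= 0.02,
           uv_t < 6e-4,
           uv_r / uv_t > 25,
           gr_r / gr_t >= 0.7 & gr_r / gr_t <= 1.3,
           all(optics$R_u$value + optics$T_leaf$value <= 1 + 1e-9)))
  if (strict && !all(checks$ok))
    stop("leaf spectra violate constraints: ",
         paste(checks$name[!checks$ok], collapse = ", "), call. = FALSE)
  if (strict) invisible(checks) else checks
}

#' Generate synthetic leaf optical spectra
#'
#' Builds smooth parametric reflectance and transmittance curves (sums of
#' logistic cut-ons and a Gaussian chlorophyll window) satisfying the
#' band constraints of [validate_leaf_optics()]. The lower-surface
#' reflectance is the upper-surface curve brightened in the visible band.
#' Randomness (amplitude jitter) comes from the current RNG state; set
#' the seed for reproducible draws or use `jitter_sd = 0` in `params` for
#' the deterministic default curve.
#'
#' @param params An [leaf_spectrum_params()].
#' @param wl Wavelength grid.
#' @param litter Optional litter reflectance [lc_spectrum]; generated by
#'   [synth_litter_reflectance()] when missing.
#' @return A validated [leaf_optics()].
#' @export
synth_leaf_optics <- function(params = leaf_spectrum_params(),
                              wl = default_grid(), litter = NULL) {
  stopifnot(inherits(params, "lc_leaf_params"))
  j <- function(x) x * exp(stats::rnorm(1, 0, params$jitter_sd))
  R_u <- j(params$uv_refl) +
    j(params$blue_refl) * logistic(wl, 412, 12) +
    j(params$green_refl) * gauss(wl, params$green_peak, 30) +
    j(params$red_edge_refl) * logistic(wl, 678, 8)
  T_leaf <- j(params$uv_trans) +
    j(params$blue_trans) * logistic(wl, 420, 8) +
    j(params$green_trans) * gauss(wl, params$green_peak + 5, 33) +
    j(params$red_edge_trans) * logistic(wl, 680, 8)
  R_l <- pmin(R_u * (1 + params$lower_brighten * logistic(wl, 450, 25)), 1)
  if (is.null(litter)) litter <- synth_litter_reflectance(wl)
  out <- leaf_optics(lc_spectrum(wl, R_u), lc_spectrum(wl, R_l),
                     lc_spectrum(wl, T_leaf), litter)
  validate_leaf_optics(out, strict = TRUE)
  out
}

#' Generate a synthetic leaf-litter reflectance spectrum
#'
#' Dry brown litter: smooth, monotone increasing with wavelength, dark in
#' the UV and moderate in the red. Level and slope are mildly randomized
#' from the current RNG state.
#'
#' @param wl Wavelength grid.
#' @param jitter_sd Relative jitter of the curve level (0 = none).
#' @return An [lc_spectrum] in \[0, 1\].
#' @export
synth_litter_reflectance <- function(wl = default_grid(), jitter_sd = 0.05) {
  amp <- 0.27 * exp(stats::rnorm(1, 0, jitter_sd))
  mid <- 580 + stats::rnorm(1, 0, 10 * (jitter_sd > 0))
  lc_spectrum(wl, pmin(0.03 + amp * logistic(wl, mid, 60), 1))
}

#' Generate daylight-like synthetic illumination spectra
#'
#' Stands in for the standard terrestrial irradiance tables when none is
#' supplied: a direct solar spectrum with a steep atmospheric (ozone)
#' fall-off below about 320 nm, a clear-sky spectrum enriched at short
#' wavelengths by Rayleigh-like `1/lambda^4` weighting, and the overcast
#' spectrum derived from the cloud-index machinery at `CL`. Units are
#' photon-flux-proportional; absolute scale is arbitrary because every
#' downstream quantity is a ratio.
#'
#' @param wl Wavelength grid.
#' @param sky_fraction Broad-band ratio of sky hemispherical to direct
#'   solar irradiance at 450 nm.
#' @param CL Total cloud index of the stored overcast spectrum.
#' @return An [illumination_set()] with provenance `"synthetic"`.
#' @export
synth_illumination <- function(wl = default_grid(), sky_fraction = 0.25,
                               CL = 0.8) {
  solar <- gauss(wl, 580, 280) * logistic(wl, 318, 9)
  sky <- sky_fraction * solar * (450 / wl)^4
  illumination_set(lc_spectrum(wl, solar, unit = "irradiance"),
                   lc_spectrum(wl, sky, unit = "irradiance"),
                   CL = CL, provenance = "synthetic")
}

#' Generate synthetic multispectral-camera component spectra
#'
#' Smooth sensor quantum efficiency, lens transmittance and IR-block
#' transmittance curves, all strictly positive across 300-700 nm so that
#' the target-filter division is well posed everywhere.
#'
#' @param wl Wavelength grid.
#' @return List of [lc_spectrum]: `sensor_qe`, `lens_t`, `irblock_t`.
#' @export
synth_camera_components <- function(wl = default_grid()) {
  list(
    sensor_qe = lc_spectrum(wl, 0.25 + 0.35 * gauss(wl, 520, 160)),
    lens_t = lc_spectrum(wl, 0.92 * logistic(wl, 295, 10)),
    irblock_t = lc_spectrum(wl, 0.88 * (1 - 0.30 * logistic(wl, 690, 15))))
}

#' Bundle every input the optical model needs, synthetically
#'
#' @param wl Wavelength grid.
#' @param cone_params Cone parameter table (see [avian_cone_params()]).
#' @param fp A [fresnel_params()].
#' @return List of class `lc_model_inputs` with `illum`, `leaf_bank`
#'   (deciduous and rainforest [leaf_optics()] built from the
#'   deterministic default curves), `cones`, `camera`, `fp`, `wl`.
#' @export
synth_model_inputs <- function(wl = default_grid(),
                               cone_params = avian_cone_params(),
                               fp = fresnel_params()) {
  litter <- synth_litter_reflectance(wl, jitter_sd = 0)
  leaf_bank <- list(
    deciduous = synth_leaf_optics(
      leaf_spectrum_params("deciduous", jitter_sd = 0), wl, litter),
    rainforest = synth_leaf_optics(
      leaf_spectrum_params("rainforest", jitter_sd = 0), wl, litter))
  structure(list(illum = synth_illumination(wl), leaf_bank = leaf_bank,
                 cones = build_cones(cone_params, wl),
                 camera = synth_camera_components(wl), fp = fp, wl = wl),
            class = "lc_model_inputs")
}

#' Configuration for the synthetic selection-dataset generator
#'
#' @param n_plants Named integer vector: plants per habitat. The default
#'   habitats mirror a progression from open to closed vegetation.
#' @param openness Named list of `c(lo, hi)` ranges: the canopy-cover
#'   (`p_l`) prior of each habitat.
#' @param pixels_per_selection Pixels drawn per plant per surface.
#' @param noise_cv Coefficient of variation of the multiplicative pixel
#'   noise (0 = noiseless).
#' @param specular Include the specular terms in the forward model that
#'   generates the plants.
#' @return A list of class `lc_dataset_config`.
#' @export
dataset_config <- function(n_plants = c(deciduous = 30, wet_schlerophyll = 30,
                                        rainforest = 30),
                           openness = list(deciduous = c(0, 0.7),
                                           wet_schlerophyll = c(0.3, 0.9),
                                           rainforest = c(0.7, 1)),
                           pixels_per_selection = 40,
                           noise_cv = 0.1,
                           specular = TRUE) {
  stopifnot(all(n_plants >= 1), pixels_per_selection >= 1, noise_cv >= 0,
            all(names(n_plants) %in% names(openness)))
  structure(list(n_plants = n_plants, openness = openness,
                 pixels_per_selection = pixels_per_selection,
                 noise_cv = noise_cv, specular = specular),
            class = "lc_dataset_config")
}

#' Generate a synthetic pixel-selection dataset
#'
#' Runs the forward optical model once per plant (scene drawn from the
#' habitat's canopy-cover prior, all other parameters randomized) to
#' obtain per-channel upper- and lower-surface quantum catches through
#' the six camera channels, then emits pixel values as multiplicative
#' log-normal noise around each catch and mean-normalizes per simulated
#' photograph. Ground-truth catches and contrasts are stored alongside so
#' tests can assert recovery. Randomness comes from the current RNG
#' state.
#'
#' @param config A [dataset_config()].
#' @param inputs An `lc_model_inputs` bundle (default: fresh synthetic
#'   inputs).
#' @return An `lc_selection_dataset` (see [load_selection_dataset()])
#'   with a `ground_truth` data.frame attached.
#' @export
synth_selection_dataset <- function(config = dataset_config(),
                                    inputs = synth_model_inputs()) {
  stopifnot(inherits(config, "lc_dataset_config"))
  channels <- names(inputs$cones)
  sens <- lapply(inputs$cones, function(co)
    trapz_weights(inputs$wl) * co$net$value)
  sd_log <- sqrt(log(1 + config$noise_cv^2))
  plants <- list()
  truth <- list()
  plant_id <- 0L
  for (hab in names(config$n_plants)) {
    for (k in seq_len(config$n_plants[[hab]])) {
      plant_id <- plant_id + 1L
      rng <- config$openness[[hab]]
      scenes <- sample_scenes(1, overrides = list(
        p_l = stats::runif(1, rng[1], rng[2])))
      scene <- scene_from_row(scenes[1, ])
      rad <- leaf_radiances(scene, inputs$illum,
                            inputs$leaf_bank[[scene$leaf_kind]], inputs$fp,
                            specular = config$specular)
      q_u <- vapply(sens, function(w) sum(w * rad$upper$value), numeric(1))
      q_l <- vapply(sens, function(w) sum(w * rad$lower$value), numeric(1))
      npx <- config$pixels_per_selection
      px_u <- lapply(channels, function(ch)
        q_u[[ch]] * exp(stats::rnorm(npx, 0, sd_log)))
      px_l <- lapply(channels, function(ch)
        q_l[[ch]] * exp(stats::rnorm(npx, 0, sd_log)))
      names(px_u) <- names(px_l) <- channels
      # each plant is its own simulated photograph: mean-normalize per channel
      for (ch in channels) {
        m <- mean(c(px_u[[ch]], px_l[[ch]]))
        px_u[[ch]] <- px_u[[ch]] / m
        px_l[[ch]] <- px_l[[ch]] / m
      }
      plants[[plant_id]] <- list(
        plant_id = sprintf("plant%03d", plant_id),
        image_id = sprintf("img%03d", plant_id),
        habitat = hab,
        sunlit = scene$d == 1,
        upper = px_u, lower = px_l)
      truth[[plant_id]] <- data.frame(
        plant_id = sprintf("plant%03d", plant_id), habitat = hab,
        channel = channels,
        Q_u = unname(q_u), Q_l = unname(q_l),
        C = (q_u - q_l) / (q_u + q_l), row.names = NULL)
    }
  }
  ds <- structure(list(channels = channels, plants = plants,
                       normalized = TRUE),
                  class = "lc_selection_dataset")
  attr(ds, "ground_truth") <- do.call(rbind, truth)
  ds
}
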