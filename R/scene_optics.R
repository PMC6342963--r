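#' Scene parameters for one model iteration
#'
#' The twelve habitat/environment parameters that the Monte-Carlo driver
#' randomizes. The modelled geometry is an observer with a horizontal
#' gaze looking at two identical leaves side by side, one tilted toward
#' the observer (its upper surface is seen) and one tilted away (its
#' lower surface is seen); all other reflective surfaces (canopy leaves,
#' litter) are horizontal.
#'
#' @param theta_z Solar zenith angle, degrees, \[0, 90).
#' @param theta_l Leaf tilt from the zenith, degrees, \[70, 90\] by
#'   default (near-vertical leaves seen side-on).
#' @param gamma_s Sun azimuth relative to the gaze direction, degrees.
#' @param p_c Proportion of the sky occluded by clouds.
#' @param d 0/1: whether direct sun reaches the modelled leaves.
#' @param p_l Proportion of the sky occluded by overlying canopy
#'   ("canopy cover").
#' @param p_s Occlusion of the solar disc by clouds (0 = fully occluded,
#'   1 = unoccluded).
#' @param p_g Proportion of the ground (litter) visible through the
#'   understory below.
#' @param source_above Extended source mirrored by the upper leaf
#'   surface: `"sky"`, `"cloud"` or `"canopy"`.
#' @param source_below Extended source mirrored by the lower leaf
#'   surface: `"litter"` or `"leaves"`.
#' @param d_r 0/1: direct sun on the below-source surface.
#' @param leaf_kind `"deciduous"` or `"rainforest"` (selects which leaf
#'   spectra are used).
#' @return A validated list of class `lc_scene`.
#' @export
scene_params <- function(theta_z = 45, theta_l = 80, gamma_s = 0,
                         p_c = 0, d = 1, p_l = 0, p_s = 1, p_g = 1,
                         source_above = "sky", source_below = "litter",
                         d_r = 1, leaf_kind = "deciduous") {
  if (theta_z < 0 || theta_z >= 90)
    stop("theta_z must lie in [0, 90)", call. = FALSE)
  if (theta_l < 0 || theta_l > 90)
    stop("theta_l must lie in [0, 90] degrees", call. = FALSE)
  for (p in c(p_c, p_l, p_s, p_g))
    if (p < 0 || p > 1) stop("fractions must lie in [0, 1]", call. = FALSE)
  if (!d %in% c(0, 1) || !d_r %in% c(0, 1))
    stop("d and d_r are 0/1 indicators", call. = FALSE)
  source_above <- match.arg(source_above, c("sky", "cloud", "canopy"))
  source_below <- match.arg(source_below, c("litter", "leaves"))
  leaf_kind <- match.arg(leaf_kind, c("deciduous", "rainforest"))
  structure(list(theta_z = theta_z, theta_l = theta_l, gamma_s = gamma_s,
                 p_c = p_c, d = d, p_l = p_l, p_s = p_s, p_g = p_g,
                 source_above = source_above, source_below = source_below,
                 d_r = d_r, leaf_kind = leaf_kind),
            class = "lc_scene")
}

#' Leaf and litter optical spectra
#'
#' @param R_u Upper-surface diffuse reflectance ([lc_spectrum]).
#' @param R_l Lower-surface diffuse reflectance.
#' @param T_leaf Diffuse transmittance; `R_u + T_leaf` must not exceed 1.
#' @param R_g Leaf-litter reflectance.
#' @return A validated list of class `lc_leaf_optics`.
#' @export
leaf_optics <- function(R_u, R_l, T_leaf, R_g) {
  stopifnot(is_spectrum(R_u), is_spectrum(R_l), is_spectrum(T_leaf),
            is_spectrum(R_g))
  stop_if_grid_mismatch(R_u, R_l, T_leaf, R_g)
  if (any(R_u$value + T_leaf$value > 1 + 1e-9))
    stop("R_u + T must not exceed 1 (energy conservation)", call. = FALSE)
  structure(list(R_u = R_u, R_l = R_l, T_leaf = T_leaf, R_g = R_g),
            class = "lc_leaf_optics")
}

#' Fresnel parameters of the leaf cuticle
#'
#' @param n1 Refractive index of air (1).
#' @param n2 Refractive index of the leaf surface (1.45, taken constant
#'   over 300-700 nm).
#' @param K Multiplicative correction factor for surface roughness;
#'   measured leaf values span 0.6-3.5, 1 is conservative.
#' @return A validated list of class `lc_fresnel`.
#' @export
fresnel_params <- function(n1 = 1, n2 = 1.45, K = 1) {
  if (!(n2 > n1 && n1 > 0)) stop("need n2 > n1 > 0", call. = FALSE)
  if (K < 0.6 || K > 3.5) stop("K must lie in [0.6, 3.5]", call. = FALSE)
  structure(list(n1 = n1, n2 = n2, K = K), class = "lc_fresnel")
}

#' Angle of incidence of the sun on a tilted leaf
#'
#' The leaf normal and the solar ray are built by rotation products: the
#' leaf (tilt `theta_l` from the zenith, seen side-on by a horizontal
#' gaze) has unit normal `(0, cos theta_l, -sin theta_l)`; the sun ray at
#' zenith angle `theta_z` and azimuth `gamma_s` relative to the gaze is
#' `(-sin theta_z sin gamma_s, sin theta_z cos gamma_s, -cos theta_z)`.
#' For the leaf tilted away from the observer the azimuth is shifted by
#' 180 degrees. `theta_s` is the angle between ray and normal; values of
#' 90 degrees or more mean the sun misses the leaf's upper surface.
#'
#' @param theta_z Solar zenith angle, degrees.
#' @param theta_l Leaf tilt from the zenith, degrees.
#' @param gamma_s Sun azimuth relative to the gaze, degrees.
#' @param facing `"toward"` or `"away"`: which of the two modelled leaves.
#' @return List with `n_vec`, `r_vec`, `theta_s` (degrees) and
#'   `sun_missed` (logical).
#' @export
sun_incidence_angle <- function(theta_z, theta_l, gamma_s,
                                facing = c("toward", "away")) {
  facing <- match.arg(facing)
  if (facing == "away") gamma_s <- gamma_s - 180
  n_vec <- c(0, cos_deg(theta_l), -sin_deg(theta_l))
  r_vec <- c(-sin_deg(theta_z) * sin_deg(gamma_s),
             sin_deg(theta_z) * cos_deg(gamma_s),
             -cos_deg(theta_z))
  dp <- min(max(sum(r_vec * n_vec), -1), 1)
  theta_s <- acos(dp) * 180 / pi
  list(n_vec = n_vec, r_vec = r_vec, theta_s = theta_s,
       sun_missed = theta_s >= 90)
}

# shared sky/cloud/canopy-filtered components of downwelling irradiance;
# numeric vectors on the illumination grid
downwelling_components <- function(scene, illum, optics, I_c = NULL) {
  if (is.null(I_c))
    I_c <- overcast_sky_irradiance(illum, scene$theta_z, illum$CL)
  I_sky <- (1 - scene$p_c) * (1 - scene$p_l) * illum$I_b$value
  I_cld <- scene$p_c * (1 - scene$p_l) * I_c$value
  I_t <- scene$p_l * ((1 - scene$p_c) * illum$I_b$value +
                        scene$p_c * I_c$value +
                        scene$p_s * illum$I_s$value * cos_deg(scene$theta_z)) *
    optics$T_leaf$value
  list(I_sky = I_sky, I_cld = I_cld, I_t = I_t, I_c = I_c)
}

#' Downwelling irradiance incident on one modelled leaf
#'
#' Sums the sky, cloud, direct-sun and canopy-filtered contributions:
#' `I_sky = (1 - p_c)(1 - p_l) I_b`, `I_cld = p_c (1 - p_l) I_c`,
#' `I_sun = d p_s I_s cos(theta_s)` (zero when the sun misses the leaf)
#' and `I_t = p_l ((1 - p_c) I_b + p_c I_c + p_s I_s cos(theta_z)) T`.
#' The direct-sun term depends on the leaf's own incidence angle, so the
#' toward- and away-facing leaves get different totals.
#'
#' @param scene An [scene_params()].
#' @param illum An [illumination_set()].
#' @param optics A [leaf_optics()].
#' @param theta_s Incidence angle of the sun on this leaf, degrees (from
#'   [sun_incidence_angle()]).
#' @param sun_missed Logical: the sun misses this leaf's upper surface
#'   (forces the direct term to zero).
#' @return List of [lc_spectrum]: `I_sky`, `I_cld`, `I_sun`, `I_t`,
#'   `I_down`.
#' @export
downwelling <- function(scene, illum, optics, theta_s, sun_missed = FALSE) {
  comp <- downwelling_components(scene, illum, optics)
  d <- if (sun_missed) 0 else scene$d
  I_sun <- d * scene$p_s * illum$I_s$value * cos_deg(theta_s)
  wl <- illum$I_b$wl
  sp <- function(v) lc_spectrum(wl, v, unit = "irradiance")
  list(I_sky = sp(comp$I_sky), I_cld = sp(comp$I_cld), I_sun = sp(I_sun),
       I_t = sp(comp$I_t), I_down = sp(comp$I_sky + comp$I_cld + I_sun +
                                         comp$I_t))
}

#' Upwelling irradiance below the modelled leaves
#'
#' Downwelling light reaching the horizontal surfaces below (litter with
#' probability-weight `p_g`, understory leaves otherwise) and diffusely
#' reflected back up:
#' `I_up = (I_sky + I_cld + (1 - p_l) p_s I_s cos(theta_z) + I_t)
#'          (p_g R_g + (1 - p_g) R_u)`.
#'
#' @inheritParams downwelling
#' @return An [lc_spectrum] with the irradiance unit.
#' @export
upwelling <- function(scene, illum, optics) {
  comp <- downwelling_components(scene, illum, optics)
  direct <- (1 - scene$p_l) * scene$p_s * illum$I_s$value *
    cos_deg(scene$theta_z)
  refl <- scene$p_g * optics$R_g$value + (1 - scene$p_g) * optics$R_u$value
  lc_spectrum(illum$I_b$wl,
              (comp$I_sky + comp$I_cld + direct + comp$I_t) * refl,
              unit = "irradiance")
}

#' Diffuse (Lambertian) radiances leaving the two leaves
#'
#' `L_u_d = I_down R_u / pi` off the toward leaf's upper surface,
#' `L_t = I_down T / pi` transmitted through the away leaf, and
#' `L_l_d = I_up R_l / pi` off the away leaf's lower surface. The two
#' `I_down` arguments differ only in their direct-sun terms.
#'
#' @param I_down_toward,I_down_away Downwelling irradiance
#'   ([lc_spectrum]) on the toward- and away-facing leaf.
#' @param I_up Upwelling irradiance below the leaves.
#' @param optics A [leaf_optics()].
#' @return List of radiance [lc_spectrum]: `L_u_d`, `L_t`, `L_l_d`.
#' @export
diffuse_radiances <- function(I_down_toward, I_down_away, I_up, optics) {
  stop_if_grid_mismatch(I_down_toward, I_down_away, I_up, optics$R_u)
  wl <- I_up$wl
  list(
    L_u_d = lc_spectrum(wl, I_down_toward$value * optics$R_u$value / pi,
                        unit = "radiance"),
    L_t = lc_spectrum(wl, I_down_away$value * optics$T_leaf$value / pi,
                      unit = "radiance"),
    L_l_d = lc_spectrum(wl, I_up$value * optics$R_l$value / pi,
                        unit = "radiance"))
}

#' Fresnel reflectance components of the leaf cuticle
#'
#' Horizontally (`R_s`) and vertically (`R_p`) polarized reflectance of a
#' smooth dielectric surface at incidence angle `theta_i`, each scaled by
#' the roughness correction `K`. With the horizontal-gaze geometry the
#' incidence angle of the mirrored extended source equals the leaf tilt
#' `theta_l`.
#'
#' @param theta_i Angle of incidence, degrees, in \[0, 90\].
#' @param fp A [fresnel_params()].
#' @return List with scalars `R_s` and `R_p`.
#' @export
fresnel_components <- function(theta_i, fp = fresnel_params()) {
  if (theta_i < 0 || theta_i > 90)
    stop("theta_i must lie in [0, 90] degrees", call. = FALSE)
  n1 <- fp$n1; n2 <- fp$n2
  ct <- cos_deg(theta_i)
  root <- sqrt(1 - (n1 / n2 * sin_deg(theta_i))^2)
  R_s <- fp$K * ((n1 * ct - n2 * root) / (n1 * ct + n2 * root))^2
  R_p <- fp$K * ((n1 * root - n2 * ct) / (n1 * root + n2 * ct))^2
  list(R_s = R_s, R_p = R_p)
}

#' Radiance of the extended sources mirrored by the leaf surfaces
#'
#' The upper surface mirrors sky, cloud deck or overlying canopy; each
#' source's radiance is its irradiance contribution divided by the solid
#' angle fraction it occupies times pi, which reduces to `I_b / pi`,
#' `I_c / pi` and `I_t / (p_l pi)` respectively. The lower surface
#' mirrors litter or understory leaves, whose radiance is the downwelling
#' light at ground level (with its own direct-sun indicator `d_r`) times
#' the surface reflectance, over pi.
#'
#' @inheritParams downwelling
#' @return List of radiance [lc_spectrum]: `L_sls_above`, `L_sls_below`.
#' @export
specular_source_radiance <- function(scene, illum, optics) {
  comp <- downwelling_components(scene, illum, optics)
  wl <- illum$I_b$wl
  above <- switch(scene$source_above,
    sky = illum$I_b$value / pi,
    cloud = comp$I_c$value / pi,
    canopy = {
      if (scene$p_l <= 0)
        stop("source_above = canopy is impossible when p_l = 0",
             call. = FALSE)
      comp$I_t / (scene$p_l * pi)
    })
  ground_irr <- comp$I_sky + comp$I_cld + comp$I_t +
    scene$d_r * scene$p_s * illum$I_s$value * cos_deg(scene$theta_z)
  below <- switch(scene$source_below,
    litter = ground_irr * optics$R_g$value / pi,
    leaves = ground_irr * optics$R_u$value / pi)
  list(L_sls_above = lc_spectrum(wl, above, unit = "radiance"),
       L_sls_below = lc_spectrum(wl, below, unit = "radiance"))
}

#' Specularly reflected radiance
#'
#' Unpolarized mirror reflection of an extended source:
#' `L = 0.5 (R_s + R_p) L_source`.
#'
#' @param R_s,R_p Polarized Fresnel reflectance components (scalars).
#' @param L_source Radiance [lc_spectrum] of the mirrored source.
#' @return A radiance [lc_spectrum].
#' @export
specular_radiance <- function(R_s, R_p, L_source) {
  stopifnot(R_s >= 0, R_p >= 0, is_spectrum(L_source))
  lc_spectrum(L_source$wl, 0.5 * (R_s + R_p) * L_source$value,
              unit = "radiance")
}

#' Full radiometry of the two modelled leaves
#'
#' Composes the sun geometry, downwelling and upwelling irradiance,
#' diffuse radiances and (optionally) the specular components into the
#' complete record of what the observer sees: the toward leaf's upper
#' surface radiates `L_u_d + L_u_s`; the away leaf's lower surface
#' radiates `L_l_d + L_t + L_l_s`.
#'
#' @inheritParams downwelling
#' @param fp A [fresnel_params()].
#' @param specular If `FALSE`, the specular terms are zero (diffuse-only
#'   configuration).
#' @return List of class `lc_leaf_radiances` with radiance spectra
#'   `L_u_d`, `L_u_s`, `L_t`, `L_l_d`, `L_l_s`, `L_sls_above`,
#'   `L_sls_below`, the totals `upper` and `lower`, and the two
#'   [sun_incidence_angle()] geometries.
#' @export
leaf_radiances <- function(scene, illum, optics, fp = fresnel_params(),
                           specular = TRUE) {
  stopifnot(inherits(scene, "lc_scene"))
  geom_t <- sun_incidence_angle(scene$theta_z, scene$theta_l, scene$gamma_s,
                                "toward")
  geom_a <- sun_incidence_angle(scene$theta_z, scene$theta_l, scene$gamma_s,
                                "away")
  dw_t <- downwelling(scene, illum, optics, geom_t$theta_s, geom_t$sun_missed)
  dw_a <- downwelling(scene, illum, optics, geom_a$theta_s, geom_a$sun_missed)
  I_up <- upwelling(scene, illum, optics)
  dif <- diffuse_radiances(dw_t$I_down, dw_a$I_down, I_up, optics)
  wl <- illum$I_b$wl
  zero <- lc_spectrum(wl, numeric(length(wl)), unit = "radiance")
  if (specular) {
    fr <- fresnel_components(scene$theta_l, fp)
    sls <- specular_source_radiance(scene, illum, optics)
    L_u_s <- specular_radiance(fr$R_s, fr$R_p, sls$L_sls_above)
    L_l_s <- specular_radiance(fr$R_s, fr$R_p, sls$L_sls_below)
  } else {
    sls <- list(L_sls_above = zero, L_sls_below = zero)
    L_u_s <- zero
    L_l_s <- zero
  }
  structure(list(
    L_u_d = dif$L_u_d, L_u_s = L_u_s, L_t = dif$L_t,
    L_l_d = dif$L_l_d, L_l_s = L_l_s,
    L_sls_above = sls$L_sls_above, L_sls_below = sls$L_sls_below,
    upper = lc_spectrum(wl, dif$L_u_d$value + L_u_s$value, unit = "radiance"),
    lower = lc_spectrum(wl, dif$L_l_d$value + dif$L_t$value + L_l_s$value,
                        unit = "radiance"),
    geometry_toward = geom_t, geometry_away = geom_a,
    I_down_toward = dw_t$I_down, I_down_away = dw_a$I_down, I_up = I_up),
    class = "lc_leaf_radiances")
}
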