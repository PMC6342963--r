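#' Bundle solar and sky irradiance spectra
#'
#' @param I_s Direct normal solar irradiance ([lc_spectrum], irradiance
#'   unit).
#' @param I_b Clear-sky hemispherical irradiance (sun excluded).
#' @param CL Total cloud index used for the stored overcast spectrum
#'   (default 0.8, typical of overcast conditions).
#' @param theta_z_ref Solar zenith angle (degrees) at which the stored
#'   overcast spectrum `I_c` is evaluated; the Monte-Carlo driver
#'   recomputes `I_c` from each iteration's own zenith angle.
#' @param provenance `"standard-table"` or `"synthetic"`.
#' @return An object of class `lc_illumination` with fields `I_s`, `I_b`,
#'   `I_c`, `CL`, `provenance`.
#' @export
illumination_set <- function(I_s, I_b, CL = 0.8, theta_z_ref = 0,
                             provenance = c("synthetic", "standard-table")) {
  provenance <- match.arg(provenance)
  stopifnot(is_spectrum(I_s), is_spectrum(I_b))
  if (I_s$unit != "irradiance" || I_b$unit != "irradiance")
    stop("illumination spectra must carry the irradiance unit", call. = FALSE)
  stop_if_grid_mismatch(I_s, I_b)
  out <- structure(list(I_s = I_s, I_b = I_b, I_c = NULL, CL = CL,
                        provenance = provenance),
                   class = "lc_illumination")
  out$I_c <- overcast_sky_irradiance(out, theta_z_ref, CL)
  out
}

#' Spectral cloud index
#'
#' Converts a total (broadband) cloud index `CL` into a
#' wavelength-dependent multiplier
#' `cl(lambda) = A(CL) lambda + B(CL)` with
#' `A = 0.00150 CL (1 - CL)` and `B = 0.966 CL^2 + 0.0619 CL - 0.0389`,
#' clamped below at 0 (B is negative for small CL and a negative
#' irradiance multiplier is unphysical).
#'
#' @param CL Total cloud index in \[0, 1\].
#' @param wl Wavelength grid (nm).
#' @return Dimensionless [lc_spectrum] (not bounded above by 1).
#' @export
spectral_cloud_index <- function(CL, wl = default_grid()) {
  if (CL < 0 || CL > 1) stop("CL must lie in [0, 1]", call. = FALSE)
  A <- 0.00150 * CL * (1 - CL)
  B <- 0.966 * CL^2 + 0.0619 * CL - 0.0389
  lc_spectrum(wl, pmax(A * wl + B, 0), bounded = FALSE)
}

#' Hemispherical irradiance of an overcast sky
#'
#' Clear-sky hemispherical irradiance including the sun,
#' `I_cs = I_b + I_s cos(theta_z)`, multiplied by the spectral cloud
#' index.
#'
#' @param illum An [illumination_set()].
#' @param theta_z Solar zenith angle, degrees, in \[0, 90\].
#' @param CL Total cloud index in \[0, 1\].
#' @return An [lc_spectrum] with the irradiance unit.
#' @export
overcast_sky_irradiance <- function(illum, theta_z, CL = 0.8) {
  stopifnot(inherits(illum, "lc_illumination"))
  if (theta_z < 0 || theta_z > 90)
    stop("theta_z must lie in [0, 90] degrees", call. = FALSE)
  cl <- spectral_cloud_index(CL, illum$I_b$wl)
  ics <- illum$I_b$value + illum$I_s$value * cos_deg(theta_z)
  lc_spectrum(illum$I_b$wl, ics * cl$value, unit = "irradiance")
}

#' Radiance of an extended source from its hemispherical irradiance
#'
#' Extended sources (sky, cloud deck, canopy) are treated as uniform
#' radiators, so radiance per steradian is irradiance divided by pi.
#'
#' @param I An [lc_spectrum] with the irradiance unit.
#' @return An [lc_spectrum] with the radiance unit.
#' @export
radiance_from_irradiance <- function(I) {
  stopifnot(is_spectrum(I))
  if (I$unit != "irradiance")
    stop("input must carry the irradiance unit", call. = FALSE)
  lc_spectrum(I$wl, I$value / pi, unit = "radiance")
}

#' Read a standard terrestrial irradiance table
#'
#' Expects the layout of the ASTM G173-style reference spectra: columns
#' wavelength (nm), direct normal irradiance and hemispherical irradiance
#' on a 37-degree tilted surface. The clear-sky component is the
#' hemispherical column minus the direct column, clamped at 0. Values are
#' resampled onto `wl`. Tables supplied in energy units are converted to
#' photon-proportional units by multiplying by wavelength (a
#' proportionality constant is immaterial because every downstream
#' quantity is a ratio).
#'
#' @param path File path.
#' @param wl Target wavelength grid.
#' @param energy_units If `TRUE` (default), multiply by lambda to convert
#'   W m^-2 nm^-1 style tables to photon-flux-proportional units.
#' @param CL,theta_z_ref Passed to [illumination_set()].
#' @return An [illumination_set()].
#' @export
read_irradiance_table <- function(path, wl = default_grid(),
                                  energy_units = TRUE, CL = 0.8,
                                  theta_z_ref = 0) {
  tab <- read_numeric_table(path, min_cols = 3)
  w <- tab[[1]]
  direct <- tab[[2]]
  hemi <- tab[[3]]
  if (energy_units) {
    direct <- direct * w
    hemi <- hemi * w
  }
  I_s <- resample(lc_spectrum(w, direct, unit = "irradiance"), wl)
  I_a <- resample(lc_spectrum(w, hemi, unit = "irradiance"), wl)
  I_b <- lc_spectrum(wl, pmax(I_a$value - I_s$value, 0), unit = "irradiance")
  illumination_set(I_s, I_b, CL = CL, theta_z_ref = theta_z_ref,
                   provenance = "standard-table")
}

cos_deg <- function(x) cospi(x / 180)
sin_deg <- function(x) sinpi(x / 180)
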