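#' Visual-pigment spectral sensitivity template (A1 nomogram)
#'
#' Absorbance template for vitamin-A1 visual pigments in the standard
#' alpha + beta band form. The alpha band is
#' `1 / (exp(A(a - x)) + exp(B(b - x)) + exp(C(c - x)) + D)` with
#' `x = lambda_max / lambda`, constants `A = 69.7`, `B = 28`, `C = -14.9`,
#' `D = 0.674`, `b = 0.922`, `c = 1.104` and
#' `a = 0.8795 + 0.0459 exp(-(lambda_max - 300)^2 / 11940)`. The beta band
#' is a Gaussian `A_beta exp(-((lambda - lm_beta)/b_beta)^2)` with
#' `A_beta = 0.26`, `lm_beta = 189 + 0.315 lambda_max`,
#' `b_beta = -40.5 + 0.195 lambda_max`. The sum is renormalized to peak 1.
#'
#' @param lambda_max Peak wavelength of the pigment, nm; template validity
#'   restricted to 330-620 nm.
#' @param wl Wavelength grid (nm), default [default_grid()].
#' @param beta_band Include the beta (short-wavelength) band; on by default.
#' @return An [lc_spectrum] of sensitivity, peak-normalized to 1.
#' @export
opsin_nomogram <- function(lambda_max, wl = default_grid(), beta_band = TRUE) {
  if (lambda_max < 330 || lambda_max > 620)
    stop("lambda_max outside the template validity range [330, 620] nm",
         call. = FALSE)
  x <- lambda_max / wl
  a <- 0.8795 + 0.0459 * exp(-(lambda_max - 300)^2 / 11940)
  alpha <- 1 / (exp(69.7 * (a - x)) + exp(28 * (0.922 - x)) +
                  exp(-14.9 * (1.104 - x)) + 0.674)
  s <- alpha
  if (beta_band) {
    lm_b <- 189 + 0.315 * lambda_max
    b_b <- -40.5 + 0.195 * lambda_max
    s <- s + 0.26 * exp(-((wl - lm_b) / b_b)^2)
  }
  lc_spectrum(wl, s / max(s))
}

#' Oil-droplet spectral transmittance template
#'
#' Avian cone oil droplets act as long-pass cut-off filters. The template
#' is a Gompertz curve `T(lambda) = exp(-exp(-k (lambda - lambda_cut)))`
#' parameterized by the 50%-transmittance wavelength `lambda_mid` and the
#' slope `B_mid` of the curve at that point: `k = B_mid / (0.5 ln 2)` and
#' `lambda_cut = lambda_mid + ln(ln 2)/k`, so that
#' `T(lambda_mid) = 0.5` exactly and `T'(lambda_mid) = B_mid`.
#'
#' @param lambda_mid Wavelength of 50% transmittance, nm; must lie inside
#'   the grid.
#' @param wl Wavelength grid (nm).
#' @param b_mid Slope of the transmittance curve at `lambda_mid`, per nm.
#'   Measured droplets span roughly 0.02-0.12 nm^-1.
#' @return An [lc_spectrum] of transmittance in \[0, 1\].
#' @export
oil_droplet_transmittance <- function(lambda_mid, wl = default_grid(),
                                      b_mid = 0.04) {
  if (lambda_mid < min(wl) || lambda_mid > max(wl))
    stop("lambda_mid must lie within the wavelength grid", call. = FALSE)
  stopifnot(b_mid > 0)
  k <- b_mid / (0.5 * log(2))
  lambda_cut <- lambda_mid + log(log(2)) / k
  lc_spectrum(wl, exp(-exp(-k * (wl - lambda_cut))))
}

#' Sigmoidal ocular-media transmittance
#'
#' Smooth UV cut-on curve standing in for the combined cornea + lens +
#' vitreous transmittance of a bird eye. Birds with a U-type (UVS) cone
#' have media transmitting further into the UV than birds with a V-type
#' (VS) cone.
#'
#' @param lambda_on Wavelength of 50% transmittance of the cut-on, nm.
#' @param wl Wavelength grid (nm).
#' @param scale Logistic width, nm.
#' @return An [lc_spectrum] of transmittance in \[0, 1\].
#' @export
ocular_media <- function(lambda_on, wl = default_grid(), scale = 8) {
  lc_spectrum(wl, stats::plogis((wl - lambda_on) / scale))
}

#' Assemble a cone spectral sensitivity
#'
#' Multiplies the opsin absorbance by the oil-droplet transmittance (when
#' present; U- and V-cones have transparent droplets) and the ocular-media
#' transmittance, then peak-normalizes. The `net` spectrum therefore
#' already contains the media factor: quantum catches computed from it
#' must not apply media a second time.
#'
#' @param cone_class Tag, one of `"U"`, `"V"`, `"S(U)"`, `"S(V)"`, `"M"`,
#'   `"L"` (free-form tags are allowed for theoretical systems).
#' @param opsin [lc_spectrum] from [opsin_nomogram()].
#' @param media [lc_spectrum] of ocular-media transmittance.
#' @param droplet Optional [lc_spectrum] of oil-droplet transmittance, or
#'   `NULL` for transparent droplets.
#' @param lambda_max,lambda_mid Bookkeeping copies of the template
#'   parameters (optional).
#' @return An object of class `lc_cone` with fields `cone_class`,
#'   `lambda_max`, `lambda_mid`, `opsin`, `droplet`, `media`, `net`.
#' @export
assemble_cone <- function(cone_class, opsin, media, droplet = NULL,
                          lambda_max = NA_real_, lambda_mid = NA_real_) {
  stopifnot(is_spectrum(opsin), is_spectrum(media))
  if (is.null(droplet)) {
    stop_if_grid_mismatch(opsin, media)
    v <- opsin$value * media$value
  } else {
    stopifnot(is_spectrum(droplet))
    stop_if_grid_mismatch(opsin, media, droplet)
    v <- opsin$value * droplet$value * media$value
  }
  if (max(v) <= 0) stop("assembled sensitivity is identically zero", call. = FALSE)
  structure(
    list(cone_class = cone_class, lambda_max = lambda_max,
         lambda_mid = lambda_mid, opsin = opsin, droplet = droplet,
         media = media, net = lc_spectrum(opsin$wl, v / max(v))),
    class = "lc_cone")
}

#' @export
print.lc_cone <- function(x, ...) {
  cat(sprintf("<lc_cone> class %s, lambda_max %s nm, oil droplet: %s\n",
              x$cone_class,
              ifelse(is.na(x$lambda_max), "?", format(x$lambda_max)),
              if (is.null(x$droplet)) "transparent" else
                sprintf("lambda_mid %s nm", format(x$lambda_mid))))
  invisible(x)
}

#' Default avian cone template parameters
#'
#' Representative peak and droplet parameters for the six cone classes of
#' UVS- and VS-type terrestrially foraging birds. These are configuration,
#' not measurements: edit the returned table (or supply a file via
#' [read_cone_params()]) to model a particular species. U- and V-cones
#' have transparent oil droplets (`lambda_mid = NA`); their ocular media
#' differ (UV cut-on 320 vs 350 nm) and the M- and L-cones use the mean of
#' the two media curves.
#'
#' @return A data.frame with columns `cone_class`, `lambda_max`,
#'   `lambda_mid`, `media` (tag: `"U"`, `"V"` or `"mean"`).
#' @export
avian_cone_params <- function() {
  data.frame(
    cone_class = c("U", "V", "S(U)", "S(V)", "M", "L"),
    lambda_max = c(371, 405, 445, 470, 505, 565),
    lambda_mid = c(NA, NA, 415, 435, 515, 570),
    media = c("U", "V", "U", "V", "mean", "mean"),
    stringsAsFactors = FALSE)
}

#' Read a cone parameter table
#'
#' Delimited text with columns `cone_class`, `lambda_max`, `lambda_mid`
#' (empty or NA for transparent droplets) and `media` (`U`, `V` or
#' `mean`); `#` comments allowed.
#'
#' @param path File path.
#' @return A data.frame in the layout of [avian_cone_params()].
#' @export
read_cone_params <- function(path) {
  tab <- utils::read.table(path, header = TRUE, comment.char = "#",
                           stringsAsFactors = FALSE)
  need <- c("cone_class", "lambda_max", "lambda_mid", "media")
  if (!all(need %in% names(tab)))
    stop("cone parameter file must have columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  tab[need]
}

#' Build the full avian cone set
#'
#' @param params Parameter table as from [avian_cone_params()].
#' @param wl Wavelength grid.
#' @param media_u,media_v Ocular media 50% cut-on wavelengths (nm) of the
#'   U-type and V-type eye.
#' @param beta_band Include the nomogram beta band.
#' @return Named list of [assemble_cone()] objects, keyed by cone class.
#' @export
build_cones <- function(params = avian_cone_params(), wl = default_grid(),
                        media_u = 320, media_v = 350, beta_band = TRUE) {
  m_u <- ocular_media(media_u, wl)
  m_v <- ocular_media(media_v, wl)
  m_mean <- lc_spectrum(wl, (m_u$value + m_v$value) / 2)
  media_bank <- list(U = m_u, V = m_v, mean = m_mean)
  cones <- lapply(seq_len(nrow(params)), function(i) {
    p <- params[i, ]
    droplet <- if (is.na(p$lambda_mid)) NULL else
      oil_droplet_transmittance(p$lambda_mid, wl)
    assemble_cone(p$cone_class,
                  opsin_nomogram(p$lambda_max, wl, beta_band = beta_band),
                  media_bank[[p$media]], droplet,
                  lambda_max = p$lambda_max, lambda_mid = p$lambda_mid)
  })
  names(cones) <- params$cone_class
  cones
}

#' Target filter transmittance for a multispectral camera channel
#'
#' Divides a cone's net spectral sensitivity by the combined spectral
#' response of the camera (sensor quantum efficiency x lens transmittance
#' x IR-blocking filter transmittance), so that the camera fitted with the
#' filter mimics the cone. The quotient is renormalized to peak 1 and
#' clipped to \[0, 1\].
#'
#' @param cone An `lc_cone`.
#' @param camera List with [lc_spectrum] fields `sensor_qe`, `lens_t`,
#'   `irblock_t`, all on the cone's grid (see [synth_camera_components()]).
#' @return An [lc_spectrum]: the filter transmittance.
#' @export
camera_target_filter <- function(cone, camera) {
  stopifnot(inherits(cone, "lc_cone"))
  stop_if_grid_mismatch(cone$net, camera$sensor_qe, camera$lens_t,
                        camera$irblock_t)
  denom <- camera$sensor_qe$value * camera$lens_t$value * camera$irblock_t$value
  num <- cone$net$value
  bad <- denom <= 0 & num > 0
  if (any(bad))
    stop("camera response is zero where the cone is sensitive: ",
         "target filter is unachievable", call. = FALSE)
  f <- ifelse(denom > 0, num / denom, 0)
  f <- f / max(f)
  lc_spectrum(cone$net$wl, pmin(pmax(f, 0), 1))
}

#' Weber fractions from relative cone abundances
#'
#' Receptor-channel noise scales with the inverse square root of the
#' number of receptors feeding an integrative unit:
#' `omega_i = nu / sqrt(eta_i)`, with the common constant `nu` calibrated
#' so that a chosen anchor class takes a chosen value.
#'
#' @param ratios Named numeric vector of relative cone abundances, e.g.
#'   `c(L = 3, M = 2.5, "S(U)" = 1.7, U = 1)`.
#' @param anchor_class Name of the anchor class (must appear in `ratios`).
#' @param anchor_value Weber fraction assigned to the anchor class.
#' @return Named numeric vector of Weber fractions in the order of
#'   `ratios`.
#' @examples
#' weber_fractions(c(L = 3, M = 2.5, S = 1.7, U = 1))
#' @export
weber_fractions <- function(ratios, anchor_class = "L", anchor_value = 0.069) {
  stopifnot(length(ratios) >= 1, all(ratios > 0))
  if (is.null(names(ratios)) || !anchor_class %in% names(ratios))
    stop("`ratios` must be named and include the anchor class", call. = FALSE)
  if (anchor_value <= 0)
    stop("`anchor_value` must be positive", call. = FALSE)
  nu <- anchor_value * sqrt(ratios[[anchor_class]])
  out <- nu / sqrt(ratios)
  names(out) <- names(ratios)
  out
}

#' Bundle cones, Weber fractions and abundances into a visual system
#'
#' @param cones Named list of `lc_cone` objects (or of [lc_spectrum]
#'   effective sensitivities).
#' @param weber Named numeric vector of Weber fractions, one per cone.
#' @param ratios Optional named relative abundances.
#' @return An object of class `lc_visual_system`.
#' @export
visual_system <- function(cones, weber, ratios = NULL) {
  stopifnot(length(cones) >= 1, !is.null(names(cones)))
  if (anyDuplicated(names(cones)))
    stop("cone classes must be unique", call. = FALSE)
  if (!all(names(cones) %in% names(weber)))
    stop("`weber` must name every cone class", call. = FALSE)
  if (any(weber <= 0)) stop("Weber fractions must be positive", call. = FALSE)
  structure(list(cones = cones, weber = weber[names(cones)], ratios = ratios),
            class = "lc_visual_system")
}
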