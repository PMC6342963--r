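#' Monte-Carlo configuration
#'
#' @param n_iter Number of iterations (default 10,000).
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @param specular Include the specular reflection terms (turn off for
#'   the diffuse-only configuration).
#' @param overrides Named list fixing scene parameters: a scalar fixes
#'   the value, a length-2 numeric gives a uniform sampling range.
#' @return A list of class `lc_mc_config`.
#' @export
mc_config <- function(n_iter = 10000, seed = NULL, specular = TRUE,
                      overrides = list()) {
  stopifnot(n_iter >= 1)
  structure(list(n_iter = as.integer(n_iter), seed = seed,
                 specular = specular, overrides = overrides),
            class = "lc_mc_config")
}

#' Draw randomized scene parameters
#'
#' Samples the twelve habitat/environment parameters:
#' `theta_z ~ U[0, 90)`, `theta_l ~ U[70, 90]`, `gamma_s ~ U[0, 360)`,
#' the occlusion fractions `p_c, p_l, p_s, p_g ~ U[0, 1]`,
#' `d ~ Bernoulli(1/2)`, the upper specular source categorical with
#' probabilities `(p_l, (1 - p_l) p_c, (1 - p_l)(1 - p_c))` over
#' (canopy, cloud, sky), the lower source `(p_g, 1 - p_g)` over
#' (litter, leaves), `d_r ~ Bernoulli((1 - p_l) p_s)` and a fair coin
#' over leaf kind. Overridden fields take their fixed value (or uniform
#' range). Uses the current RNG state.
#'
#' @param n Number of scenes.
#' @param overrides Named list of fixed values or length-2 ranges.
#' @return Data.frame with one row per scene and the twelve parameter
#'   columns.
#' @export
sample_scenes <- function(n, overrides = list()) {
  draw <- function(name, lo, hi) {
    ov <- overrides[[name]]
    if (is.null(ov)) return(stats::runif(n, lo, hi))
    if (length(ov) == 2) return(stats::runif(n, ov[1], ov[2]))
    rep(ov, length.out = n)
  }
  draw_bin <- function(name, prob) {
    ov <- overrides[[name]]
    if (is.null(ov)) return(as.numeric(stats::runif(n) < prob))
    rep(ov, length.out = n)
  }
  theta_z <- draw("theta_z", 0, 90)
  theta_z[theta_z >= 90] <- 89.999
  theta_l <- draw("theta_l", 70, 90)
  gamma_s <- draw("gamma_s", 0, 360)
  p_c <- draw("p_c", 0, 1)
  p_l <- draw("p_l", 0, 1)
  p_s <- draw("p_s", 0, 1)
  p_g <- draw("p_g", 0, 1)
  d <- draw_bin("d", 0.5)
  d_r <- draw_bin("d_r", (1 - p_l) * p_s)
  source_above <- overrides[["source_above"]]
  if (is.null(source_above)) {
    u <- stats::runif(n)
    source_above <- ifelse(u < p_l, "canopy",
                           ifelse(u < p_l + (1 - p_l) * p_c, "cloud", "sky"))
  } else source_above <- rep(source_above, length.out = n)
  source_below <- overrides[["source_below"]]
  if (is.null(source_below)) {
    source_below <- ifelse(stats::runif(n) < p_g, "litter", "leaves")
  } else source_below <- rep(source_below, length.out = n)
  leaf_kind <- overrides[["leaf_kind"]]
  if (is.null(leaf_kind)) {
    leaf_kind <- ifelse(stats::runif(n) < 0.5, "deciduous", "rainforest")
  } else leaf_kind <- rep(leaf_kind, length.out = n)
  data.frame(theta_z = theta_z, theta_l = theta_l, gamma_s = gamma_s,
             p_c = p_c, d = d, p_l = p_l, p_s = p_s, p_g = p_g,
             source_above = source_above, source_below = source_below,
             d_r = d_r, leaf_kind = leaf_kind, stringsAsFactors = FALSE)
}

scene_from_row <- function(row) {
  scene_params(theta_z = row$theta_z, theta_l = row$theta_l,
               gamma_s = row$gamma_s, p_c = row$p_c, d = row$d,
               p_l = row$p_l, p_s = row$p_s, p_g = row$p_g,
               source_above = row$source_above,
               source_below = row$source_below,
               d_r = row$d_r, leaf_kind = row$leaf_kind)
}

#' Run one Monte-Carlo iteration
#'
#' Computes the leaf radiances for a scene, the U- and V-cone quantum
#' catches of the two visible surfaces, their Michelson contrasts, the
#' relative performance `R = C_V - C_U` and the UV-band (300-400 nm)
#' specular:diffuse radiance ratio of the upper surface.
#'
#' @param scene An [scene_params()] (or one row of [sample_scenes()]).
#' @param inputs An `lc_model_inputs` bundle (see [synth_model_inputs()]).
#' @param specular Include specular components.
#' @param uv_band Wavelength band of the specular:diffuse ratio.
#' @return One-row data.frame: `C_U`, `C_V`, `R`, `spec_diff_ratio`, and
#'   the attached `radiances` record as an attribute.
#' @export
run_iteration <- function(scene, inputs, specular = TRUE,
                          uv_band = c(300, 400)) {
  if (is.data.frame(scene)) scene <- scene_from_row(scene[1, ])
  optics <- inputs$leaf_bank[[scene$leaf_kind]]
  rad <- leaf_radiances(scene, inputs$illum, optics, inputs$fp,
                        specular = specular)
  w <- trapz_weights(inputs$wl)
  wU <- w * inputs$cones$U$net$value
  wV <- w * inputs$cones$V$net$value
  C_U <- michelson(sum(wU * rad$upper$value), sum(wU * rad$lower$value))
  C_V <- michelson(sum(wV * rad$upper$value), sum(wV * rad$lower$value))
  dif <- band_mean(rad$L_u_d, uv_band[1], uv_band[2])
  spc <- band_mean(rad$L_u_s, uv_band[1], uv_band[2])
  out <- data.frame(C_U = C_U, C_V = C_V, R = C_V - C_U,
                    spec_diff_ratio = if (dif > 0) spc / dif else
                      (if (spc > 0) Inf else 0))
  attr(out, "radiances") <- rad
  out
}

#' Run the randomized optical model
#'
#' Draws `n_iter` scenes (reproducibly from the seed), evaluates the
#' radiometric model for each and records the per-iteration contrasts.
#' Identical `(seed, config, inputs)` always give identical runs.
#'
#' @param config An [mc_config()].
#' @param inputs An `lc_model_inputs` bundle.
#' @return Data.frame of class `lc_model_run`: the twelve scene columns
#'   plus `C_U`, `C_V`, `R` and `spec_diff_ratio`; the configuration is
#'   attached as attribute `config`.
#' @export
run_model <- function(config = mc_config(), inputs = synth_model_inputs()) {
  stopifnot(inherits(config, "lc_mc_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  scenes <- sample_scenes(config$n_iter, config$overrides)
  w <- trapz_weights(inputs$wl)
  wU <- w * inputs$cones$U$net$value
  wV <- w * inputs$cones$V$net$value
  uv <- inputs$wl >= 300 & inputs$wl <= 400
  w_uv <- trapz_weights(inputs$wl[uv])
  uv_width <- diff(range(inputs$wl[uv]))
  C_U <- C_V <- ratio <- numeric(config$n_iter)
  for (i in seq_len(config$n_iter)) {
    scene <- scene_from_row(scenes[i, ])
    optics <- inputs$leaf_bank[[scene$leaf_kind]]
    rad <- leaf_radiances(scene, inputs$illum, optics, inputs$fp,
                          specular = config$specular)
    C_U[i] <- michelson(sum(wU * rad$upper$value), sum(wU * rad$lower$value))
    C_V[i] <- michelson(sum(wV * rad$upper$value), sum(wV * rad$lower$value))
    dif <- sum(w_uv * rad$L_u_d$value[uv]) / uv_width
    spc <- sum(w_uv * rad$L_u_s$value[uv]) / uv_width
    ratio[i] <- if (dif > 0) spc / dif else (if (spc > 0) Inf else 0)
  }
  out <- cbind(scenes, data.frame(C_U = C_U, C_V = C_V, R = C_V - C_U,
                                  spec_diff_ratio = ratio))
  attr(out, "config") <- config
  class(out) <- c("lc_model_run", "data.frame")
  out
}

#' Canopy-cover crossover of the V-cone advantage
#'
#' Bins the run's records by canopy cover `p_l` (default
#' 10-percentage-point bins) and returns the lowest bin boundary above
#' which the median of `R = C_V - C_U` is positive in every higher bin.
#' Records can first be restricted to one upper specular source. If the
#' median never changes sign across the bins (for example in a
#' diffuse-only run, where the U-cone always wins), the no-crossover
#' sentinel `NA` is returned.
#'
#' @param run An `lc_model_run`.
#' @param bin_width Width of the `p_l` bins.
#' @param condition_source Restrict to records with this `source_above`
#'   (`NULL` keeps all).
#' @param min_records Minimum records required after conditioning.
#' @return Crossover canopy-cover fraction, or `NA` (no crossover).
#' @export
canopy_crossover <- function(run, bin_width = 0.1,
                             condition_source = "canopy",
                             min_records = 1000) {
  stopifnot(inherits(run, "lc_model_run") || is.data.frame(run))
  rec <- run
  if (!is.null(condition_source))
    rec <- rec[rec$source_above == condition_source, ]
  if (nrow(rec) < min_records)
    stop("only ", nrow(rec), " records after conditioning; need at least ",
         min_records, call. = FALSE)
  breaks <- seq(0, 1, by = bin_width)
  bin <- cut(rec$p_l, breaks, include.lowest = TRUE, labels = FALSE)
  med <- tapply(rec$R, bin, stats::median)
  idx <- as.integer(names(med))
  if (all(med > 0) || all(med <= 0)) return(NA_real_)
  pos_from <- rev(cumprod(rev(med > 0))) == 1 # bins where all higher medians > 0
  if (!any(pos_from)) return(NA_real_)
  breaks[idx[which(pos_from)[1]]]
}

#' Median V-cone advantage by upper specular light source
#'
#' @param run An `lc_model_run` (specular-enabled).
#' @return Data.frame with one row per `source_above`: record count,
#'   lower quartile, median and upper quartile of `R`.
#' @export
summarize_by_source <- function(run) {
  stopifnot(is.data.frame(run))
  src <- sort(unique(run$source_above))
  out <- do.call(rbind, lapply(src, function(s) {
    r <- run$R[run$source_above == s]
    data.frame(source_above = s, n = length(r),
               q25 = stats::quantile(r, 0.25, names = FALSE),
               median = stats::median(r),
               q75 = stats::quantile(r, 0.75, names = FALSE))
  }))
  rownames(out) <- NULL
  out
}

#' Bin-median trends linking canopy cover, specular:diffuse ratio and R
#'
#' Two monotone relationships characterize the mechanism: the UV-band
#' specular:diffuse radiance ratio of the upper leaf surface grows with
#' canopy cover, and the V-cone advantage `R` grows with that ratio.
#' Both trends are evaluated among records whose upper specular source is
#' the overlying canopy (the mechanism under study); across sources the
#' ratio is driven by the source identity instead — the sky is UV-bright,
#' canopy-filtered light UV-dark — which would mask the canopy-cover
#' effect.
#'
#' @param run An `lc_model_run`.
#' @param n_bins Number of bins (at least 8 for a stable trend).
#' @param condition_source Upper specular source restriction (`NULL`
#'   keeps all records).
#' @return List of two data.frames: `ratio_by_pl` (`bin_lo`, `bin_hi`,
#'   `n`, `median_ratio`) and `R_by_ratio` (`bin`, `n`, `median_ratio`,
#'   `median_R`).
#' @export
specular_ratio_trend <- function(run, n_bins = 10,
                                 condition_source = "canopy") {
  stopifnot(is.data.frame(run), n_bins >= 2)
  rec <- run[is.finite(run$spec_diff_ratio), ]
  if (!is.null(condition_source))
    rec <- rec[rec$source_above == condition_source, ]
  breaks <- seq(0, 1, length.out = n_bins + 1)
  bin <- cut(rec$p_l, breaks, include.lowest = TRUE, labels = FALSE)
  ratio_by_pl <- do.call(rbind, lapply(sort(unique(bin)), function(b) {
    r <- rec$spec_diff_ratio[bin == b]
    data.frame(bin_lo = breaks[b], bin_hi = breaks[b + 1], n = length(r),
               median_ratio = stats::median(r))
  }))
  rec2 <- rec
  qs <- stats::quantile(rec2$spec_diff_ratio,
                        probs = seq(0, 1, length.out = n_bins + 1))
  qs <- unique(qs)
  bin2 <- cut(rec2$spec_diff_ratio, qs, include.lowest = TRUE, labels = FALSE)
  R_by_ratio <- do.call(rbind, lapply(sort(unique(bin2)), function(b) {
    sel <- bin2 == b
    data.frame(bin = b, n = sum(sel),
               median_ratio = stats::median(rec2$spec_diff_ratio[sel]),
               median_R = stats::median(rec2$R[sel]))
  }))
  list(ratio_by_pl = ratio_by_pl, R_by_ratio = R_by_ratio)
}

#' Median monochromatic leaf-contrast spectrum under open or closed canopy
#'
#' Repeats the radiometric model with the upper specular source fixed to
#' overlying canopy, restricted to open (`p_l` below the split) or closed
#' (`p_l` above it) canopies, takes the per-wavelength median of the
#' upper- and lower-surface radiances across iterations and returns their
#' Michelson contrast wavelength by wavelength over 300-500 nm.
#'
#' @param inputs An `lc_model_inputs` bundle.
#' @param canopy_band `"open"` or `"closed"`.
#' @param split Canopy-cover split point (0.8).
#' @param n_iter Iterations.
#' @param seed Optional seed.
#' @param band Wavelength window of the returned contrast spectrum.
#' @param specular Include specular components.
#' @return Data.frame: `wl`, `median_upper`, `median_lower`, `contrast`.
#' @export
contrast_spectrum <- function(inputs, canopy_band = c("open", "closed"),
                              split = 0.8, n_iter = 2000, seed = NULL,
                              band = c(300, 500), specular = TRUE) {
  canopy_band <- match.arg(canopy_band)
  if (!is.null(seed)) set.seed(seed)
  pl_range <- if (canopy_band == "closed") c(split, 1) else c(0.01, split)
  scenes <- sample_scenes(n_iter, overrides = list(
    p_l = pl_range, source_above = "canopy"))
  keep <- inputs$wl >= band[1] & inputs$wl <= band[2]
  up <- matrix(0, n_iter, sum(keep))
  lo <- matrix(0, n_iter, sum(keep))
  for (i in seq_len(n_iter)) {
    rad <- leaf_radiances(scene_from_row(scenes[i, ]), inputs$illum,
                          inputs$leaf_bank[[scenes$leaf_kind[i]]],
                          inputs$fp, specular = specular)
    up[i, ] <- rad$upper$value[keep]
    lo[i, ] <- rad$lower$value[keep]
  }
  med_u <- apply(up, 2, stats::median)
  med_l <- apply(lo, 2, stats::median)
  data.frame(wl = inputs$wl[keep], median_upper = med_u,
             median_lower = med_l,
             contrast = (med_u - med_l) / (med_u + med_l))
}

#' Write a model run to a delimited table
#'
#' @param run An `lc_model_run`.
#' @param path Output path (tab-separated).
#' @return `path`, invisibly.
#' @export
write_model_run <- function(run, path) {
  utils::write.table(as.data.frame(run), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
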