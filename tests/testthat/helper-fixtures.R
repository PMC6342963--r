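# shared fixtures: small grids, flat spectra, toy datasets, oracles

flat_spec <- function(value, wl = default_grid(), unit = "dimensionless") {
  lc_spectrum(wl, rep(value, length(wl)), unit = unit,
              bounded = identical(unit, "dimensionless") && value <= 1)
}

flat_illumination <- function(I_s = 1, I_b = 1, wl = default_grid(), ...) {
  illumination_set(flat_spec(I_s, wl, "irradiance"),
                   flat_spec(I_b, wl, "irradiance"), ...)
}

flat_optics <- function(R_u = 0.1, R_l = 0.12, T_leaf = 0.05, R_g = 0.2,
                        wl = default_grid()) {
  leaf_optics(flat_spec(R_u, wl), flat_spec(R_l, wl),
              flat_spec(T_leaf, wl), flat_spec(R_g, wl))
}

# brute-force sign-test oracle: exhaustive enumeration of all 2^n equally
# likely sign patterns
brute_sign_p <- function(s, n) {
  stopifnot(n <= 16)
  counts <- choose(n, 0:n)
  lower <- sum(counts[seq_len(s + 1)]) / 2^n        # P(S <= s)
  upper <- sum(counts[seq(s + 1, n + 1)]) / 2^n     # P(S >= s)
  min(1, 2 * min(lower, upper))
}

# build a selection dataset by hand from per-plant pixel lists
make_dataset <- function(plants, channels) {
  structure(list(channels = channels, plants = plants, normalized = TRUE),
            class = "lc_selection_dataset")
}

make_plant <- function(id, habitat, upper, lower, sunlit = FALSE) {
  list(plant_id = id, image_id = paste0("img_", id), habitat = habitat,
       sunlit = sunlit, upper = upper, lower = lower)
}

# receptor-noise-limited closed forms written out independently
rnl_tri <- function(df, e) {
  sqrt((e[1]^2 * (df[3] - df[2])^2 + e[2]^2 * (df[3] - df[1])^2 +
          e[3]^2 * (df[1] - df[2])^2) /
         ((e[1] * e[2])^2 + (e[1] * e[3])^2 + (e[2] * e[3])^2))
}

rnl_tetra <- function(df, e) {
  num <- (e[1] * e[2])^2 * (df[4] - df[3])^2 +
    (e[1] * e[3])^2 * (df[4] - df[2])^2 +
    (e[1] * e[4])^2 * (df[3] - df[2])^2 +
    (e[2] * e[3])^2 * (df[4] - df[1])^2 +
    (e[2] * e[4])^2 * (df[3] - df[1])^2 +
    (e[3] * e[4])^2 * (df[2] - df[1])^2
  den <- (e[1] * e[2] * e[3])^2 + (e[1] * e[2] * e[4])^2 +
    (e[1] * e[3] * e[4])^2 + (e[2] * e[3] * e[4])^2
  sqrt(num / den)
}
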