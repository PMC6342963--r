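test_that("sun incidence angle reproduces the rotation-product geometry", {
  # zenith sun on a horizontal leaf: normal incidence, azimuth-invariant
  for (g in c(0, 77, 200)) {
    expect_equal(sun_incidence_angle(0, 90, g)$theta_s, 0, tolerance = 1e-9)
  }
  # zenith sun, leaf tilted 70 deg from zenith: arccos(sin 70)
  expect_equal(sun_incidence_angle(0, 70, 10)$theta_s, 20, tolerance = 1e-9)
  # periodic in azimuth; away-facing leaf equals toward at gamma - 180
  g1 <- sun_incidence_angle(40, 80, 123)
  expect_equal(g1$theta_s, sun_incidence_angle(40, 80, 123 + 360)$theta_s)
  expect_equal(sun_incidence_angle(40, 80, 123, "away")$theta_s,
               sun_incidence_angle(40, 80, 123 - 180, "toward")$theta_s)
  # unit vectors
  expect_equal(sum(g1$n_vec^2), 1)
  expect_equal(sum(g1$r_vec^2), 1)
  # sun behind the leaf is flagged
  expect_true(sun_incidence_angle(80, 70, 180)$sun_missed)
})

test_that("downwelling irradiance follows the component bookkeeping", {
  wl <- default_grid()
  ill <- flat_illumination(1, 1)
  op <- flat_optics(T_leaf = 0.5)
  # full canopy blocks all direct sky and cloud light
  sc <- scene_params(p_l = 1, p_c = 0.5, theta_z = 30)
  dw <- downwelling(sc, ill, op, theta_s = 20)
  expect_true(all(dw$I_sky$value == 0))
  expect_true(all(dw$I_cld$value == 0))
  # open sky, unoccluded sun: I_down = I_b + I_s cos(theta_s)
  sc2 <- scene_params(p_c = 0, p_l = 0, d = 1, p_s = 1, theta_z = 30)
  dw2 <- downwelling(sc2, ill, op, theta_s = 60)
  expect_equal(dw2$I_down$value, rep(1 + cos(pi / 3), length(wl)),
               tolerance = 1e-12)
  # canopy-filtered term, hand evaluation with flat unit spectra:
  # p_l ((1-p_c) I_b + p_c I_c + p_s I_s cos 0) T at CL index 1
  sc3 <- scene_params(p_l = 0.5, p_c = 0.5, p_s = 1, theta_z = 0, d = 0)
  ci550 <- spectral_cloud_index(0.8)$value[wl == 550] # I_c = 2 * index
  dw3 <- downwelling(sc3, ill, op, theta_s = 0)
  expect_equal(dw3$I_t$value[wl == 550],
               0.5 * (0.5 + 0.5 * 2 * ci550 + 1) * 0.5, tolerance = 1e-12)
  # sun_missed forces the direct term to zero
  dw4 <- downwelling(sc2, ill, op, theta_s = 60, sun_missed = TRUE)
  expect_true(all(dw4$I_sun$value == 0))
})

test_that("upwelling irradiance mixes litter and understory reflectance", {
  ill <- flat_illumination(1, 0)           # sun only
  # I_sky = I_cld = I_t = 0 via p_c = 0, I_b = 0, T = 0
  op <- flat_optics(R_u = 0.1, T_leaf = 0, R_g = 0.2)
  sc <- scene_params(p_l = 0, p_s = 1, theta_z = 0, p_g = 0.5, p_c = 0)
  up <- upwelling(sc, ill, op)
  expect_equal(up$value, rep(0.15, 401), tolerance = 1e-12)
  # p_g = 1: pure litter factor; R_g = R_u makes p_g irrelevant
  sc_g1 <- scene_params(p_l = 0, p_s = 1, theta_z = 0, p_g = 1, p_c = 0)
  expect_equal(upwelling(sc_g1, ill, op)$value, rep(0.2, 401),
               tolerance = 1e-12)
  op_eq <- flat_optics(R_u = 0.2, T_leaf = 0, R_g = 0.2)
  for (pg in c(0, 0.3, 1)) {
    scx <- scene_params(p_l = 0, p_s = 1, theta_z = 0, p_g = pg, p_c = 0)
    expect_equal(upwelling(scx, ill, op_eq)$value, rep(0.2, 401),
                 tolerance = 1e-12)
  }
})

test_that("diffuse radiances are Lambertian conversions of the irradiances", {
  wl <- default_grid()
  I_flat_pi <- flat_spec(pi, wl, "irradiance")
  op <- leaf_optics(flat_spec(1, wl), flat_spec(0.02, wl),
                    flat_spec(0, wl), flat_spec(0.2, wl))
  d <- diffuse_radiances(I_flat_pi, I_flat_pi, I_flat_pi, op)
  expect_equal(d$L_u_d$value, rep(1, 401))
  expect_true(all(d$L_t$value == 0))      # opaque leaf transmits nothing
  expect_equal(d$L_l_d$value, rep(0.02, 401))
})

test_that("Fresnel components match the closed forms", {
  fr0 <- fresnel_components(0)
  expect_equal(fr0$R_s, ((1 - 1.45) / (1 + 1.45))^2, tolerance = 1e-12)
  expect_equal(fr0$R_p, fr0$R_s, tolerance = 1e-12)
  fr90 <- fresnel_components(90)
  expect_equal(fr90$R_s, 1, tolerance = 1e-12)
  expect_equal(fr90$R_p, 1, tolerance = 1e-12)
  brewster <- atan(1.45) * 180 / pi
  expect_equal(fresnel_components(brewster)$R_p, 0, tolerance = 1e-12)
  # K scales both components; grazing reflectance equals K
  frk <- fresnel_components(90, fresnel_params(K = 2.5))
  expect_equal(frk$R_s, 2.5, tolerance = 1e-12)
  # 0 <= R_p <= R_s <= 1 across (0, 90) at K = 1
  for (th in seq(5, 85, 5)) {
    fr <- fresnel_components(th)
    expect_gte(fr$R_p, 0)
    expect_lte(fr$R_p, fr$R_s)
    expect_lte(fr$R_s, 1)
  }
})

test_that("specular source radiances follow the division convention", {
  wl <- default_grid()
  ill <- flat_illumination(1, 1)
  # canopy: flat I_t = 1 needs T = 1 with p_l ((1-p_c) I_b + p_s I_s) = 1
  op <- leaf_optics(flat_spec(0, wl), flat_spec(0, wl), flat_spec(1, wl),
                    flat_spec(0.2, wl))
  sc <- scene_params(p_l = 0.5, p_c = 0, p_s = 1, theta_z = 0,
                     source_above = "canopy")
  s <- specular_source_radiance(sc, ill, op)
  expect_equal(s$L_sls_above$value, rep(2 / pi, 401), tolerance = 1e-12)
  # sky source: exactly I_b / pi, the p-fractions cancel
  sc_sky <- scene_params(p_l = 0.3, p_c = 0.4, source_above = "sky")
  s_sky <- specular_source_radiance(sc_sky, ill, op)
  expect_equal(s_sky$L_sls_above$value, ill$I_b$value / pi)
  # litter below, lit only by direct sun: R_g cos(theta_z) / pi
  op2 <- flat_optics(R_u = 0.1, T_leaf = 0, R_g = 0.2)
  ill2 <- flat_illumination(I_s = 1, I_b = 0)
  sc_lit <- scene_params(p_c = 0, p_l = 0, d_r = 1, p_s = 1, theta_z = 0,
                         source_below = "litter")
  s_lit <- specular_source_radiance(sc_lit, ill2, op2)
  expect_equal(s_lit$L_sls_below$value, rep(0.2 / pi, 401), tolerance = 1e-12)
  # canopy source with p_l = 0 is a probability-zero draw
  sc_bad <- scene_params(p_l = 0, source_above = "canopy")
  expect_error(specular_source_radiance(sc_bad, ill, op), "impossible")
})

test_that("specular radiance averages the two polarized components", {
  L <- flat_spec(1, unit = "radiance")
  expect_equal(specular_radiance(1, 1, L)$value, L$value)
  expect_true(all(specular_radiance(0, 0, L)$value == 0))
  expect_equal(specular_radiance(0.02, 0.04, L)$value, rep(0.03, 401))
})

test_that("full leaf radiances compose the equations (worked flat-spectrum scenario)", {
  wl <- default_grid()
  ill <- flat_illumination(I_s = 1, I_b = 0.3)
  op <- flat_optics(R_u = 0.1, R_l = 0.12, T_leaf = 0.05, R_g = 0.2)
  sc <- scene_params(theta_z = 30, theta_l = 75, gamma_s = 40, p_c = 0.4,
                     d = 1, p_l = 0.6, p_s = 0.7, p_g = 0.3,
                     source_above = "canopy", source_below = "litter",
                     d_r = 1)
  rad <- leaf_radiances(sc, ill, op)

  # independent scalar composition of the model equations at 550 nm
  deg <- pi / 180
  cl <- 0.0015 * 0.8 * 0.2 * 550 + (0.966 * 0.64 + 0.0619 * 0.8 - 0.0389)
  I_c <- (0.3 + 1 * cos(30 * deg)) * cl
  th_t <- acos(sin(30 * deg) * cos(40 * deg) * cos(75 * deg) +
                 cos(30 * deg) * sin(75 * deg)) / deg
  th_a <- acos(sin(30 * deg) * cos(-140 * deg) * cos(75 * deg) +
                 cos(30 * deg) * sin(75 * deg)) / deg
  I_sky <- (1 - 0.4) * (1 - 0.6) * 0.3
  I_cld <- 0.4 * (1 - 0.6) * I_c
  I_t <- 0.6 * ((1 - 0.4) * 0.3 + 0.4 * I_c + 0.7 * 1 * cos(30 * deg)) * 0.05
  sun_t <- if (th_t < 90) 0.7 * cos(th_t * deg) else 0
  sun_a <- if (th_a < 90) 0.7 * cos(th_a * deg) else 0
  I_down_t <- I_sky + I_cld + sun_t + I_t
  I_down_a <- I_sky + I_cld + sun_a + I_t
  I_up <- (I_sky + I_cld + (1 - 0.6) * 0.7 * cos(30 * deg) + I_t) *
    (0.3 * 0.2 + 0.7 * 0.1)
  root <- sqrt(1 - (sin(75 * deg) / 1.45)^2)
  R_s <- ((cos(75 * deg) - 1.45 * root) / (cos(75 * deg) + 1.45 * root))^2
  R_p <- ((root - 1.45 * cos(75 * deg)) / (root + 1.45 * cos(75 * deg)))^2
  F_avg <- 0.5 * (R_s + R_p)
  upper_550 <- I_down_t * 0.1 / pi + F_avg * I_t / (0.6 * pi)
  lower_550 <- I_up * 0.12 / pi + I_down_a * 0.05 / pi +
    F_avg * (I_sky + I_cld + I_t + 1 * 0.7 * cos(30 * deg)) * 0.2 / pi

  expect_equal(rad$upper$value[wl == 550], upper_550, tolerance = 1e-12)
  expect_equal(rad$lower$value[wl == 550], lower_550, tolerance = 1e-12)

  # diffuse-only configuration zeroes the specular terms
  rad0 <- leaf_radiances(sc, ill, op, specular = FALSE)
  expect_true(all(rad0$L_u_s$value == 0))
  expect_true(all(rad0$L_l_s$value == 0))
  expect_equal(rad0$upper$value, rad0$L_u_d$value)

  # opaque leaf over a dark understory: lower radiance is purely specular
  op_dark <- flat_optics(R_u = 0.1, R_l = 0, T_leaf = 0, R_g = 0.2)
  rad_dark <- leaf_radiances(sc, ill, op_dark)
  expect_equal(rad_dark$lower$value, rad_dark$L_l_s$value)
})

test_that("radiances scale linearly with the illumination and obey the pi bound", {
  ill <- flat_illumination(0.8, 0.4)
  ill2 <- flat_illumination(1.6, 0.8)
  op <- flat_optics()
  sc <- scene_params(theta_z = 20, theta_l = 85, gamma_s = 200, p_c = 0.3,
                     p_l = 0.5, p_s = 0.6, p_g = 0.7,
                     source_above = "canopy", source_below = "leaves")
  r1 <- leaf_radiances(sc, ill, op)
  r2 <- leaf_radiances(sc, ill2, op)
  expect_equal(r2$upper$value, 2 * r1$upper$value, tolerance = 1e-12)
  expect_equal(r2$lower$value, 2 * r1$lower$value, tolerance = 1e-12)
  # pi L_u_d <= I_down and pi L_l_d <= I_up pointwise (R <= 1)
  expect_true(all(pi * r1$L_u_d$value <= r1$I_down_toward$value + 1e-12))
  expect_true(all(pi * r1$L_l_d$value <= r1$I_up$value + 1e-12))
})
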