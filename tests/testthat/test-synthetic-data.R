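test_that("generated leaf spectra satisfy every foliage band constraint", {
  set.seed(20)
  for (kind in c("deciduous", "rainforest")) {
    for (rep in 1:5) {
      op <- synth_leaf_optics(leaf_spectrum_params(kind))
      checks <- validate_leaf_optics(op, strict = FALSE)
      expect_true(all(checks$ok), label = paste(kind, "draw", rep))
      expect_true(all(op$R_u$value >= 0 & op$R_u$value <= 1))
      expect_true(all(op$R_l$value >= 0 & op$R_l$value <= 1))
    }
  }
  # the validator rejects non-compliant spectra (UV-bright transmittance)
  wl <- default_grid()
  bad <- leaf_optics(flat_spec(0.015, wl), flat_spec(0.015, wl),
                     flat_spec(0.01, wl), flat_spec(0.2, wl))
  expect_error(validate_leaf_optics(bad), "uv_transmittance")
})

test_that("leaf generation is deterministic given the seed and varies across seeds", {
  set.seed(1); a <- synth_leaf_optics()
  set.seed(1); b <- synth_leaf_optics()
  set.seed(2); c <- synth_leaf_optics()
  expect_identical(a$R_u$value, b$R_u$value)
  expect_false(identical(a$R_u$value, c$R_u$value))
})

test_that("litter reflectance is a smooth monotone brown-material curve", {
  set.seed(22)
  r1 <- synth_litter_reflectance()
  r2 <- synth_litter_reflectance()
  expect_true(all(r1$value >= 0 & r1$value <= 1))
  expect_gte(r1$value[r1$wl == 700], r1$value[r1$wl == 300])
  expect_true(all(diff(r1$value) >= 0))
  expect_false(identical(r1$value, r2$value))  # RNG contract
})

test_that("synthetic illumination is daylight-like on the full grid", {
  ill <- synth_illumination()
  expect_true(all(ill$I_s$value > 0))
  expect_true(all(ill$I_b$value > 0))
  expect_true(all(ill$I_c$value > 0))
  # Rayleigh-like enrichment: sky/solar ratio larger in the UV than red
  ratio <- ill$I_b$value / ill$I_s$value
  expect_gt(ratio[ill$I_s$wl == 350], ratio[ill$I_s$wl == 650])
  # steep solar fall-off below the atmospheric cut-on
  expect_lt(ill$I_s$value[ill$I_s$wl == 300],
            0.2 * ill$I_s$value[ill$I_s$wl == 400])
})

test_that("camera components keep the target-filter division well posed", {
  cam <- synth_camera_components()
  for (s in cam) {
    expect_gt(min(s$value), 0)
    expect_lte(max(s$value), 1)
  }
  for (cone in build_cones())
    expect_s3_class(camera_target_filter(cone, cam), "lc_spectrum")
})

test_that("noiseless selection datasets reproduce the forward-model catches", {
  set.seed(24)
  cfg <- dataset_config(n_plants = c(deciduous = 6, rainforest = 6),
                        pixels_per_selection = 5, noise_cv = 0)
  ds <- synth_selection_dataset(cfg)
  truth <- attr(ds, "ground_truth")
  tab <- plant_contrast_table(ds)
  for (i in seq_along(ds$plants)) {
    p <- ds$plants[[i]]
    tr <- truth[truth$plant_id == p$plant_id, ]
    for (ch in ds$channels) {
      got <- tab[tab$plant_id == p$plant_id, paste0("C_", ch)]
      expect_equal(got, tr$C[tr$channel == ch], tolerance = 1e-12)
      # per-image mean normalization maps each catch to 2 Q / (Q_u + Q_l)
      qu <- tr$Q_u[tr$channel == ch]; ql <- tr$Q_l[tr$channel == ch]
      expect_equal(stats::median(p$upper[[ch]]), 2 * qu / (qu + ql),
                   tolerance = 1e-12)
    }
  }
})

test_that("the closed pipeline recovers planted channel orderings at zero noise", {
  # diffuse-only forward model: the UV channel out-contrasts the green
  # channel in every generated plant, and the pipeline reports exactly that
  set.seed(25)
  cfg <- dataset_config(n_plants = c(deciduous = 12), noise_cv = 0,
                        pixels_per_selection = 5, specular = FALSE)
  ds <- synth_selection_dataset(cfg)
  truth <- attr(ds, "ground_truth")
  planted <- sum(truth$C[truth$channel == "U"] >
                   truth$C[truth$channel == "M"])
  expect_equal(planted, 12)
  tab <- plant_contrast_table(ds)
  res <- habitat_sign_tests(tab, hypotheses = list(c("U", "M")))
  expect_equal(res$statistic, res$n)
  expect_equal(res$n, 12)

  # with specular terms on, the pipeline still agrees with the generator
  # ground truth plant by plant (zero noise leaves nothing to estimation)
  set.seed(25)
  cfg2 <- dataset_config(n_plants = c(rainforest = 10), noise_cv = 0,
                         pixels_per_selection = 5)
  ds2 <- synth_selection_dataset(cfg2)
  truth2 <- attr(ds2, "ground_truth")
  tab2 <- plant_contrast_table(ds2)
  res2 <- habitat_sign_tests(tab2, hypotheses = list(c("U", "M")))
  expect_equal(res2$statistic,
               sum(truth2$C[truth2$channel == "U"] >
                     truth2$C[truth2$channel == "M"]))
})

test_that("dataset generation is seed-reproducible end to end", {
  cfg <- dataset_config(n_plants = c(rainforest = 4),
                        pixels_per_selection = 8, noise_cv = 0.1)
  set.seed(7); inp <- synth_model_inputs()
  set.seed(30); d1 <- synth_selection_dataset(cfg, inp)
  set.seed(30); d2 <- synth_selection_dataset(cfg, inp)
  expect_identical(d1$plants, d2$plants)
})

test_that("closed-canopy habitats favor the V-cone in the generated data", {
  set.seed(26)
  cfg <- dataset_config(n_plants = c(rainforest = 25),
                        openness = list(rainforest = c(0.92, 1)),
                        noise_cv = 0, pixels_per_selection = 5)
  ds <- synth_selection_dataset(cfg)
  tab <- plant_contrast_table(ds)
  res <- habitat_sign_tests(tab, hypotheses = list(c("V", "U")))
  # under nearly closed canopies most plants show the V-cone advantage
  expect_gt(res$statistic, res$n / 2)
})
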