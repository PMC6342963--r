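test_that("image normalization subtracts dark noise and fixes the mean at 1", {
  expect_equal(normalize_image(c(1, 2, 3)), c(0.5, 1, 1.5))
  # adding a constant offset and declaring it as dark changes nothing
  px <- c(10, 20, 40, 70)
  expect_equal(normalize_image(px + 7, dark = 7), normalize_image(px))
  # unmasked output mean is exactly 1; masked pixels come back NA
  mask <- c(FALSE, TRUE, FALSE, FALSE)
  out <- normalize_image(px, mask = mask)
  expect_equal(mean(out[!mask]), 1)
  expect_true(is.na(out[2]))
  expect_error(normalize_image(c(0, 0, 0)), "zero mean")
  # positive rescaling before normalization is invisible afterwards
  expect_equal(normalize_image(3.7 * px), normalize_image(px))
})

test_that("selection datasets round-trip through JSON and are validated", {
  set.seed(14)
  cfg <- dataset_config(n_plants = c(deciduous = 3, rainforest = 3),
                        pixels_per_selection = 10, noise_cv = 0.05)
  ds <- synth_selection_dataset(cfg)
  path <- withr::local_tempfile(fileext = ".json")
  write_selection_dataset(ds, path)
  back <- load_selection_dataset(path)
  expect_equal(back$channels, ds$channels)
  expect_equal(length(back$plants), length(ds$plants))
  expect_equal(back$plants[[1]]$upper, ds$plants[[1]]$upper,
               tolerance = 1e-12)
  expect_equal(plant_contrast_table(back)[, -(1:4)],
               plant_contrast_table(ds)[, -(1:4)], tolerance = 1e-12)

  # a plant missing its lower surface is reported by name
  broken <- ds
  broken$plants[[2]]$lower <- NULL
  path2 <- withr::local_tempfile(fileext = ".json")
  write_selection_dataset(broken, path2)
  expect_error(load_selection_dataset(path2), "plant002")

  # external field names map through the adapter layer
  renamed <- jsonlite::read_json(path, simplifyVector = FALSE)
  renamed$plants <- lapply(renamed$plants, function(p) {
    p$plantName <- p$plant_id
    p$plant_id <- NULL
    p
  })
  path3 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(renamed, path3, auto_unbox = TRUE, digits = NA)
  adapted <- load_selection_dataset(path3,
                                    field_map = c(plant_id = "plantName"))
  expect_equal(adapted$plants[[1]]$plant_id, ds$plants[[1]]$plant_id)
})

test_that("per-plant contrast table computes median-based contrasts and JNDs", {
  plants <- list(
    make_plant("p1", "deciduous",
               upper = list(U = c(2, 4), M = c(1, 1)),
               lower = list(U = c(1, 1), M = c(1, 1))),
    make_plant("p2", "deciduous",
               upper = list(U = c(3, 3), M = c(2, 2)),
               lower = list(U = c(3, 3), M = c(2, 2))))
  ds <- make_dataset(plants, channels = c("U", "M"))
  tab <- plant_contrast_table(
    ds, systems = list(UM = channel_system(c("U", "M"))))
  expect_equal(tab$C_U, c(0.5, 0))       # medians 3 vs 1
  expect_equal(tab$C_M, c(0, 0))
  # identical surfaces give zero contrast and zero JND
  expect_equal(tab$JND_UM[2], 0)
  expect_equal(tab$JND_UM[1], log(3) / (0.069 * sqrt(2)), tolerance = 1e-12)
  # a system needing an absent channel is refused
  expect_error(plant_contrast_table(
    ds, systems = list(bad = channel_system(c("U", "L")))), "absent")
})

test_that("channel systems encode the two noise conventions", {
  eq <- channel_system(c("L", "M", "S(U)", "U"))
  expect_true(all(eq$weber == 0.069))
  ab <- channel_system(c("L", "M", "S(U)", "U"), equal_noise = FALSE)
  expect_equal(unname(ab$weber), c(0.069, 0.0756, 0.0917, 0.1195),
               tolerance = 1e-3)
})

test_that("habitat sign tests recover orderings planted by the generator", {
  # ten plants where channel A always beats channel B
  set.seed(15)
  plants <- lapply(1:10, function(i) {
    base <- runif(1, 0.5, 2)
    make_plant(paste0("p", i), "deciduous",
               upper = list(A = base * c(2, 2.2), B = base * c(1.2, 1.3)),
               lower = list(A = base * c(0.5, 0.6), B = base * c(1, 1.1)))
  })
  ds <- make_dataset(plants, channels = c("A", "B"))
  tab <- plant_contrast_table(ds)
  res <- habitat_sign_tests(tab, hypotheses = list(c("A", "B")))
  expect_equal(res$statistic, 10)
  expect_equal(res$n, 10)
  expect_equal(res$p, 2 / 2^10, tolerance = 1e-12)   # exact binomial
})

test_that("adding an informative channel never decreases the RNL distance", {
  set.seed(16)
  for (i in 1:20) {
    q3u <- runif(3, 0.5, 2); q3l <- runif(3, 0.5, 2)
    u_extra <- c(runif(1, 0.5, 2), runif(1, 0.5, 2))
    e3 <- rep(0.069, 3); e4 <- rep(0.069, 4)
    d3 <- rnl_color_distance(q3u, q3l, e3)
    d4 <- rnl_color_distance(c(q3u, u_extra[1]), c(q3l, u_extra[2]), e4)
    if (u_extra[1] != u_extra[2]) expect_gte(d4 + 1e-12, d3)
  }
})

test_that("false-color rendering stretches, gamma-encodes and masks", {
  m <- matrix(5, 4, 4)
  out <- render_false_color(m, m, m)
  expect_equal(dim(out), c(4, 4, 3))
  # constant input: uniform mid-gray, identical planes
  expect_true(length(unique(as.vector(out))) == 1)
  expect_gt(out[1, 1, 1], 100)
  expect_lt(out[1, 1, 1], 220)

  set.seed(17)
  r <- matrix(runif(16, 1, 10), 4); g <- matrix(runif(16, 1, 10), 4)
  b <- matrix(runif(16, 1, 10), 4)
  over <- matrix(FALSE, 4, 4); over[2, 3] <- TRUE
  under <- matrix(FALSE, 4, 4); under[4, 1] <- TRUE
  out2 <- render_false_color(r, g, b, over, under)
  expect_true(all(out2 >= 0 & out2 <= 255))
  expect_equal(out2[2, 3, ], c(255L, 255L, 255L))  # overexposed -> white
  expect_equal(out2[4, 1, ], c(0L, 0L, 0L))        # underexposed -> black
  expect_error(render_false_color(r, g, matrix(1, 2, 2)), "dimensions")
})
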