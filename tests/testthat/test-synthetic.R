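test_that("phantom generation is deterministic and validates parameters", {
  cfg <- phantom_config(n_rows = 10, n_cols = 12, n_bands = 20)
  a <- generate_phantom(9, cfg, seed = 4)
  b <- generate_phantom(9, cfg, seed = 4)
  expect_identical(a$raw$values, b$raw$values)
  expect_identical(a$white$values, b$white$values)
  expect_identical(a$dark$values, b$dark$values)

  expect_error(generate_phantom(-1, cfg, seed = 1), class = "invalid_parameter")
  expect_error(phantom_config(noise_sd_core = -0.1), class = "invalid_parameter")
  expect_error(phantom_config(wl_start = 2000, wl_end = 1000),
               class = "invalid_parameter")
  expect_error(phantom_config(absorption_centers = 5000),
               class = "invalid_parameter")
})

test_that("noiseless uniform phantoms have one identical fruit spectrum", {
  cfg <- quiet_cfg()
  ph <- generate_phantom(10, cfg, seed = 1)
  refl <- calibrate(ph$raw, ph$white, ph$dark)
  v <- refl$values
  dim(v) <- c(prod(dim(v)[1:2]), dim(v)[3])
  fruit <- v[as.vector(attr(refl, "fruit_mask")), ]
  expect_equal(max(apply(fruit, 2, function(x) diff(range(x)))), 0)
})

test_that("absorption depth grows with SSC at the band centers", {
  cfg <- quiet_cfg()
  centers <- cfg$absorption_centers
  depth_at <- function(ssc) {
    ph <- generate_phantom(ssc, cfg, seed = 1)
    refl <- calibrate(ph$raw, ph$white, ph$dark)
    spec <- mean_spectrum(refl, attr(refl, "fruit_mask"))
    vapply(centers, function(ctr)
      spec$reflectance[which.min(abs(spec$wavelengths - ctr))], 0)
  }
  lo <- depth_at(6)
  hi <- depth_at(14)
  expect_true(all(hi < lo))  # higher SSC -> deeper absorption
  # strictly monotone over a grid of SSC values, both centers
  grid <- vapply(c(6, 8, 10, 12, 14), depth_at, numeric(length(centers)))
  expect_true(all(apply(grid, 1, function(x) all(diff(x) < 0))))
})

test_that("calibration round-trip recovers the designed reflectance", {
  cfg <- phantom_config(n_rows = 20, n_cols = 20, n_bands = 40,
                        noise_sd_core = 0.01, noise_sd_edge = 0.03)
  ph <- generate_phantom(9, cfg, seed = 12)
  refl <- calibrate(ph$raw, ph$white, ph$dark, clamp = FALSE)
  err <- abs(refl$values - ph$design$values)
  sd_band <- ifelse(refl$wavelengths < 942 | refl$wavelengths > 1680,
                    cfg$noise_sd_edge, cfg$noise_sd_core)
  worst <- apply(err, 3, max) / sd_band
  expect_lt(max(worst), 5)
})

test_that("edge bands carry more noise than core bands", {
  cfg <- phantom_config(n_rows = 24, n_cols = 24, n_bands = 60,
                        noise_sd_core = 0.005, noise_sd_edge = 0.025,
                        spatial_gradient = 0, illumination_rel_sd = 0)
  ph <- generate_phantom(9, cfg, seed = 3)
  refl <- calibrate(ph$raw, ph$white, ph$dark, clamp = FALSE)
  v <- refl$values
  dim(v) <- c(prod(dim(v)[1:2]), dim(v)[3])
  fruit <- v[as.vector(attr(refl, "fruit_mask")), ]
  band_var <- apply(fruit, 2, var)
  edge <- refl$wavelengths < 942 | refl$wavelengths > 1680
  expect_gt(min(band_var[edge]), max(band_var[!edge]))
})

test_that("dataset generation honors counts, range and stratification", {
  cfg <- phantom_config(n_rows = 8, n_cols = 8, n_bands = 12)
  ds <- generate_dataset(12, c(immature = 3L, semi_mature = 5L, mature = 4L),
                         config = cfg, seed = 9, roi_size = 4)
  expect_length(ds, 12)
  tr <- dataset_truth(ds)
  expect_true(all(tr$ssc_brix >= 6 & tr$ssc_brix <= 14.1))
  expect_equal(as.vector(table(tr$maturity)[c("immature", "semi_mature", "mature")]),
               c(3L, 5L, 4L))
  # maturity strata are sorted-SSC bins
  expect_true(max(tr$ssc_brix[tr$maturity == "immature"]) <=
                min(tr$ssc_brix[tr$maturity == "semi_mature"]))
  expect_true(max(tr$ssc_brix[tr$maturity == "semi_mature"]) <=
                min(tr$ssc_brix[tr$maturity == "mature"]))
  expect_identical(dim(ds[[1]]$cube$values), c(4L, 4L, 12L))

  one <- generate_dataset(1, c(immature = 0L, semi_mature = 1L, mature = 0L),
                          config = cfg, seed = 2, roi_size = 4)
  expect_length(one, 1)
  expect_true(one[[1]]$ssc >= 6 && one[[1]]$ssc <= 14.1)

  expect_error(generate_dataset(10, c(immature = 3L, semi_mature = 5L,
                                      mature = 4L), config = cfg),
               class = "invalid_parameter")
  expect_error(generate_dataset(12, c(immature = 3L, semi_mature = 5L,
                                      mature = 4L),
                                ssc_mean = 20, config = cfg),
               class = "invalid_parameter")
  expect_error(generate_dataset(12, c(immature = 3L, semi_mature = 5L,
                                      mature = 4L),
                                ssc_range = c(14, 6), config = cfg),
               class = "invalid_parameter")
})

test_that("large-sample SSC moments match the designed truncated normal", {
  # oracle: closed-form moments of the moment-matched truncated normal say
  # the realized mean/SD should sit at the requested 9.29 / 2.17
  tiny <- phantom_config(n_rows = 6, n_cols = 6, n_bands = 16)
  ds <- generate_dataset(10000, c(immature = 2500L, semi_mature = 4200L,
                                  mature = 3300L),
                         config = tiny, seed = 31, roi_size = 2)
  ssc <- vapply(ds, `[[`, 0, "ssc")
  expect_lt(abs(mean(ssc) - 9.29), 0.1)
  expect_lt(abs(sd(ssc) - 2.17), 0.1)
})
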