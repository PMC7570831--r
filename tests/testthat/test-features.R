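test_that("ROI extraction is exact and refuses out-of-bounds requests", {
  cube <- random_cube(10, 12, 4, seed = 1)
  whole <- extract_roi(cube, center = c(5, 6), size = c(10, 12))
  expect_identical(whole$values, cube$values)

  roi <- extract_roi(cube, center = c(5, 6), size = c(4, 4))
  expect_identical(dim(roi$values), c(4L, 4L, 4L))
  expect_identical(roi$values, cube$values[4:7, 5:8, , drop = FALSE])
  expect_equal(roi$wavelengths, cube$wavelengths)

  expect_error(extract_roi(cube, center = c(1, 1), size = c(4, 4)),
               class = "out_of_bounds")
  expect_error(extract_roi(cube, center = c(5, 6), size = c(11, 4)),
               class = "out_of_bounds")
})

test_that("a 200x200 ROI comes out of a full-frame cube intact", {
  frame <- hsi_cube(array(runif(636 * 838 * 3), dim = c(636, 838, 3)),
                    c(1000, 1100, 1200))
  roi <- extract_roi(frame, center = c(318, 419), size = c(200, 200))
  expect_identical(dim(roi$values), c(200L, 200L, 3L))
})

test_that("band trimming drops 21/34 of 508 bands leaving 453 in 942-1680 nm", {
  wl <- seq(908.1, 1735.6, length.out = 508)
  prof <- spectral_profile(runif(508), wl)
  tr <- trim_bands(prof, 21, 34)
  expect_length(tr$reflectance, 453)
  expect_gte(round(min(tr$wavelengths)), 942)
  expect_lte(round(max(tr$wavelengths)), 1680)
  # index-based slice oracle
  expect_identical(tr$reflectance, prof$reflectance[22:474])

  small <- spectral_profile(1:10, seq(1000, 1090, by = 10))
  expect_identical(trim_bands(small, 2, 3)$reflectance, as.numeric(3:7))
  expect_identical(trim_bands(small, 0, 0)$reflectance, small$reflectance)
  expect_error(trim_bands(small, 5, 5), class = "invalid_parameter")

  cube <- random_cube(3, 3, 10, seed = 2, wl = seq(1000, 1090, by = 10))
  tc <- trim_bands(cube, 2, 3)
  expect_identical(tc$values, cube$values[, , 3:7, drop = FALSE])
  expect_equal(tc$wavelengths, cube$wavelengths[3:7])
})

test_that("mean spectrum equals the per-band loop-and-average oracle", {
  const <- hsi_cube(array(0.37, dim = c(3, 4, 5)),
                    seq(1000, by = 10, length.out = 5))
  expect_equal(mean_spectrum(const)$reflectance, rep(0.37, 5))

  two <- hsi_cube(array(rep(c(0.2, 0.4), 3), dim = c(2, 1, 3)),
                  c(1000, 1010, 1020))
  expect_equal(mean_spectrum(two)$reflectance, rep(0.3, 3))

  cube <- random_cube(5, 5, 8, seed = 3)
  got <- mean_spectrum(cube)$reflectance
  oracle <- numeric(8)
  for (b in 1:8) {
    acc <- 0
    for (r in 1:5) for (c in 1:5) acc <- acc + cube$values[r, c, b]
    oracle[b] <- acc / 25
  }
  expect_equal(got, oracle, tolerance = 1e-14)

  mask <- matrix(FALSE, 5, 5); mask[2, 3] <- TRUE
  expect_equal(mean_spectrum(cube, mask)$reflectance, cube$values[2, 3, ])
  expect_error(mean_spectrum(cube, matrix(FALSE, 5, 5)),
               class = "invalid_input")
})

test_that("band-window images average exactly the in-window bands", {
  wl <- seq(1040, 1100, by = 10)  # 7 bands
  cube <- random_cube(4, 4, 7, seed = 4, wl = wl)
  img <- band_window_image(cube, 1070, 20)  # closed window [1050, 1090]
  keep <- which(wl >= 1050 & wl <= 1090)
  expect_equal(attr(img, "provenance")$n_bands, length(keep))
  oracle <- apply(cube$values[, , keep], c(1, 2), mean)
  expect_equal(unclass(img)[1:4, 1:4], oracle, ignore_attr = TRUE)

  single <- band_window_image(cube, 1040, 4)
  expect_equal(unclass(single)[1:4, 1:4], cube$values[, , 1],
               ignore_attr = TRUE)
  expect_error(band_window_image(cube, 900, 5), class = "invalid_parameter")
})

test_that("image vectors average patches, block-mean downsample, flatten row-major", {
  mk <- function(x) structure(x, class = "image_patch")
  consts <- lapply(c(0.1, 0.5, 0.9), function(v) mk(matrix(v, 200, 200)))
  iv <- image_vector(consts, 28)
  expect_length(iv, 784)
  expect_equal(as.numeric(iv), rep(0.5, 784), tolerance = 1e-14)

  # 28x28 input: flatten only, row-major
  set.seed(5)
  p <- matrix(runif(28 * 28), 28, 28)
  iv2 <- image_vector(list(mk(p)), 28)
  expect_equal(as.numeric(iv2), as.vector(t(p)))

  # 56x56 checkerboard: every 2x2 block averages to 0.5
  cb <- mk(outer(1:56, 1:56, function(r, c) (r + c) %% 2))
  expect_equal(as.numeric(image_vector(list(cb), 28)), rep(0.5, 784))

  # area-weighted resample at non-divisible sizes preserves the global mean
  q <- mk(matrix(runif(200 * 200), 200, 200))
  expect_equal(mean(image_vector(list(q), 28)), mean(unclass(q)),
               tolerance = 1e-12)

  expect_error(image_vector(list(mk(matrix(0, 3, 3)), mk(matrix(0, 4, 4)))),
               class = "invalid_input")
})

test_that("min-max normalization freezes training statistics", {
  n <- feature_normalize(c(2, 4, 6))
  expect_equal(n$values, c(0, 0.5, 1))

  expect_equal(feature_normalize(c(3, 3, 3))$values, c(0, 0, 0))

  m <- cbind(a = c(2, 4, 6), b = c(1, 1, 1), c = c(1, 2, 3))
  nm <- feature_normalize(m)
  expect_equal(unname(nm$values[, 1]), c(0, 0.5, 1))
  expect_equal(unname(nm$values[, 2]), c(0, 0, 0))

  # validation values outside the training range are NOT clipped
  val <- feature_normalize(c(8, 1, 0.5), nm$stats)
  expect_gt(val$values[1], 1)
  expect_lt(val$values[3], 0)

  expect_error(feature_normalize(1:5, list(min = 1:2, max = 3:4)),
               class = "invalid_input")
})

test_that("fusion concatenates spectral-first and reports summed dims", {
  sp <- feature_vector(runif(453), "spectral")
  im <- feature_vector(runif(784), "image")
  fu <- fuse(sp, im)
  expect_length(fu, 1237)
  expect_identical(attr(fu, "kind"), "fusion")
  expect_equal(as.numeric(fu)[1:453], as.numeric(sp))
  expect_equal(as.numeric(fu)[454:1237], as.numeric(im))

  for (ab in list(c(3, 5), c(10, 2))) {
    f <- fuse(feature_vector(runif(ab[1]), "spectral"),
              feature_vector(runif(ab[2]), "image"))
    expect_length(f, sum(ab))
  }
  expect_error(fuse(im, im), class = "invalid_input")
  expect_error(fuse(sp, sp), class = "invalid_input")
})

test_that("trimming and ROI-averaging commute on the band axis", {
  cube <- random_cube(6, 6, 12, seed = 6)
  a <- trim_bands(mean_spectrum(cube), 3, 4)
  b <- mean_spectrum(trim_bands(cube, 3, 4))
  expect_equal(a$reflectance, b$reflectance, tolerance = 1e-14)
  expect_equal(a$wavelengths, b$wavelengths)
})

test_that("the feature pipeline is bit-deterministic per cube", {
  cfg <- small_phantom_cfg()
  ph <- generate_phantom(9, cfg, seed = 42)
  refl <- calibrate(ph$raw, ph$white, ph$dark)
  f1 <- sample_features(refl)
  f2 <- sample_features(refl)
  expect_identical(as.numeric(f1$fusion), as.numeric(f2$fusion))
  expect_length(f1$spectral, 453)
  expect_length(f1$image, 784)
  expect_length(f1$fusion, 1237)
})
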