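#' Extract a rectangular region of interest
#'
#' @param cube an [hsi_cube()].
#' @param center `(row, col)` of the ROI center (1-based).
#' @param size `(rows, cols)` of the ROI; must fit entirely inside the cube —
#'   no silent truncation.
#' @return sub-[hsi_cube()] of exactly `size`, wavelengths preserved. A
#'   `fruit_mask` attribute, if present, is cropped in lockstep.
#' @export
extract_roi <- function(cube, center, size) {
  if (!inherits(cube, "hsi_cube")) invalid_input("`cube` must be an hsi_cube")
  d <- dim(cube$values)
  size <- as.integer(size)
  if (any(size < 1L)) invalid_parameter("ROI size must be >= 1")
  r0 <- as.integer(center[1L]) - ceiling(size[1L] / 2L) + 1L
  c0 <- as.integer(center[2L]) - ceiling(size[2L] / 2L) + 1L
  r1 <- r0 + size[1L] - 1L
  c1 <- c0 + size[2L] - 1L
  if (r0 < 1L || c0 < 1L || r1 > d[1L] || c1 > d[2L])
    abort_class(sprintf(
      "ROI rows %d..%d, cols %d..%d exceed cube extent %d x %d",
      r0, r1, c0, c1, d[1L], d[2L]), "out_of_bounds")
  out <- hsi_cube(cube$values[r0:r1, c0:c1, , drop = FALSE],
                  cube$wavelengths, kind = cube$kind)
  m <- attr(cube, "fruit_mask")
  if (!is.null(m)) attr(out, "fruit_mask") <- m[r0:r1, c0:c1, drop = FALSE]
  out
}

#' Mean ROI spectrum and spectral profiles
#'
#' The per-band arithmetic mean of reflectance over the ROI pixels (optionally
#' restricted by a mask) is the sample's spectral signature.
#'
#' @param roi an [hsi_cube()].
#' @param mask optional logical `rows x cols` matrix selecting pixels.
#' @return object of class `spectral_profile`: list with `reflectance` and
#'   `wavelengths`.
#' @export
mean_spectrum <- function(roi, mask = NULL) {
  if (!inherits(roi, "hsi_cube")) invalid_input("`roi` must be an hsi_cube")
  d <- dim(roi$values)
  v <- roi$values
  dim(v) <- c(d[1L] * d[2L], d[3L])
  if (!is.null(mask)) {
    if (!identical(dim(mask), d[1:2]))
      invalid_input("mask shape does not match ROI")
    if (!any(mask)) invalid_input("mask selects no pixels")
    v <- v[as.vector(mask), , drop = FALSE]
  }
  spectral_profile(colMeans(v), roi$wavelengths)
}

#' @rdname mean_spectrum
#' @param reflectance per-band mean reflectance.
#' @param wavelengths band wavelengths, nm.
#' @export
spectral_profile <- function(reflectance, wavelengths) {
  if (length(reflectance) != length(wavelengths))
    invalid_input("reflectance and wavelengths lengths differ")
  structure(list(reflectance = as.numeric(reflectance),
                 wavelengths = as.numeric(wavelengths)),
            class = "spectral_profile")
}

#' Drop noisy leading/trailing bands
#'
#' Trimming is index-based (first `drop_first`, last `drop_last` bands) so the
#' retained count is exact regardless of grid rounding; under the default
#' 508-band grid, dropping 21/34 keeps the 453 bands near 942-1680 nm.
#'
#' @param x an [hsi_cube()] or [spectral_profile()].
#' @param drop_first,drop_last number of bands removed at each end
#'   (defaults 21 and 34).
#' @return same type as `x`, band and wavelength axes trimmed in lockstep.
#' @export
trim_bands <- function(x, drop_first = 21L, drop_last = 34L) {
  UseMethod("trim_bands")
}

trim_idx <- function(nb, drop_first, drop_last) {
  drop_first <- as.integer(drop_first)
  drop_last <- as.integer(drop_last)
  if (drop_first < 0L || drop_last < 0L)
    invalid_parameter("drop counts must be >= 0")
  if (drop_first + drop_last >= nb)
    invalid_parameter(sprintf("dropping %d + %d bands leaves none of %d",
                              drop_first, drop_last, nb))
  (drop_first + 1L):(nb - drop_last)
}

#' @export
trim_bands.hsi_cube <- function(x, drop_first = 21L, drop_last = 34L) {
  keep <- trim_idx(n_bands(x), drop_first, drop_last)
  out <- hsi_cube(x$values[, , keep, drop = FALSE], x$wavelengths[keep],
                  kind = x$kind)
  attr(out, "fruit_mask") <- attr(x, "fruit_mask")
  out
}

#' @export
trim_bands.spectral_profile <- function(x, drop_first = 21L, drop_last = 34L) {
  keep <- trim_idx(length(x$wavelengths), drop_first, drop_last)
  spectral_profile(x$reflectance[keep], x$wavelengths[keep])
}

#' Band-window grayscale image
#'
#' Per-pixel mean reflectance over all bands whose wavelength lies in the
#' closed window `[center_wl - half_width, center_wl + half_width]`; the
#' default windows sit on the reflectance peaks at 1070, 1270 and 1650 nm.
#'
#' @param roi an [hsi_cube()].
#' @param center_wl window center, nm.
#' @param half_width window half-width, nm (default 20, i.e. a 40-nm window).
#' @return object of class `image_patch`: `rows x cols` matrix with a
#'   `provenance` attribute describing the window.
#' @export
band_window_image <- function(roi, center_wl, half_width = 20) {
  if (!inherits(roi, "hsi_cube")) invalid_input("`roi` must be an hsi_cube")
  lo <- center_wl - half_width
  hi <- center_wl + half_width
  keep <- which(roi$wavelengths >= lo & roi$wavelengths <= hi)
  if (length(keep) == 0L)
    invalid_parameter(sprintf("no bands fall in [%g, %g] nm", lo, hi))
  px <- apply(roi$values[, , keep, drop = FALSE], c(1L, 2L), mean)
  structure(px, class = "image_patch",
            provenance = list(center_wl = center_wl, half_width = half_width,
                              n_bands = length(keep)))
}

# Area-weighted aggregation matrix mapping n_in samples onto n_out equal
# intervals; rows sum to 1. Exact block mean when n_in %% n_out == 0.
resample_weights <- function(n_in, n_out) {
  w <- matrix(0, n_out, n_in)
  step <- n_in / n_out
  for (i in seq_len(n_out)) {
    lo <- (i - 1) * step
    hi <- i * step
    j0 <- floor(lo) + 1L
    j1 <- ceiling(hi)
    for (j in j0:j1) {
      ov <- min(hi, j) - max(lo, j - 1)
      if (ov > 0) w[i, j] <- ov
    }
  }
  w / step
}

#' Image feature vector from band-window patches
#'
#' The window patches are averaged into a single grayscale patch, resampled to
#' `out_side x out_side` by area-weighted block mean, and flattened row-major
#' into a feature vector (784 values at the default 28 x 28).
#'
#' @param patches list of [band_window_image()] patches with identical shape.
#' @param out_side output side length in pixels (default 28).
#' @return [feature_vector()] of kind `"image"`.
#' @export
image_vector <- function(patches, out_side = 28L) {
  if (inherits(patches, "image_patch")) patches <- list(patches)
  dims <- lapply(patches, dim)
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1L)
    invalid_input("patches must share one shape")
  avg <- Reduce(`+`, lapply(patches, unclass)) / length(patches)
  d <- dim(avg)
  out_side <- as.integer(out_side)
  small <- if (identical(d, c(out_side, out_side))) avg else
    resample_weights(d[1L], out_side) %*% avg %*% t(resample_weights(d[2L], out_side))
  feature_vector(as.vector(t(small)), kind = "image")  # row-major flatten
}

#' Feature vector container
#'
#' @param values numeric payload.
#' @param kind `"spectral"`, `"image"` or `"fusion"`.
#' @return object of class `feature_vector` with a `kind` attribute.
#' @export
feature_vector <- function(values, kind = c("spectral", "image", "fusion")) {
  kind <- match.arg(kind)
  structure(as.numeric(values), class = "feature_vector", kind = kind)
}

#' @export
print.feature_vector <- function(x, ...) {
  cat(sprintf("<feature_vector> kind=%s, dim=%d\n", attr(x, "kind"), length(x)))
  invisible(x)
}

#' Fuse spectral and image features
#'
#' Concatenation with the spectral block first; 453 + 784 = 1237 dimensions
#' under the default configuration.
#'
#' @param spectral [feature_vector()] of kind `"spectral"` (or a
#'   [spectral_profile()], whose reflectance is taken).
#' @param image [feature_vector()] of kind `"image"`.
#' @return [feature_vector()] of kind `"fusion"`.
#' @export
fuse <- function(spectral, image) {
  if (inherits(spectral, "spectral_profile"))
    spectral <- feature_vector(spectral$reflectance, "spectral")
  if (!identical(attr(spectral, "kind"), "spectral"))
    invalid_input("first argument must be a spectral feature vector")
  if (!identical(attr(image, "kind"), "image"))
    invalid_input("second argument must be an image feature vector")
  feature_vector(c(unclass(spectral), unclass(image)), kind = "fusion")
}

#' Per-feature min-max normalization with frozen statistics
#'
#' Scales each feature to `[0, 1]` using its training-set minimum and maximum.
#' On first use (`stats = NULL`) the statistics are computed from `x` and
#' returned for reuse on validation data; validation values outside the
#' training range map outside `[0, 1]` and are not clipped. Constant features
#' map to 0.
#'
#' @param x numeric matrix (samples x features), or a numeric vector. A bare
#'   vector with `stats = NULL` is treated as one feature column over samples;
#'   with `stats` supplied and matching its length, as a single sample row.
#' @param stats optional list with `min` and `max` per feature.
#' @return list with `values` (same shape as `x`) and `stats`.
#' @export
feature_normalize <- function(x, stats = NULL) {
  was_vector <- is.null(dim(x))
  m <- if (was_vector) {
    if (is.null(stats)) matrix(x, ncol = 1L) else matrix(x, nrow = 1L)
  } else as.matrix(x)
  if (is.null(stats)) {
    stats <- list(min = apply(m, 2L, min), max = apply(m, 2L, max))
  }
  if (length(stats$min) != ncol(m) || length(stats$max) != ncol(m))
    invalid_input("stats length does not match feature count")
  rng <- stats$max - stats$min
  out <- sweep(m, 2L, stats$min, `-`)
  nz <- rng > 0
  out[, nz] <- sweep(out[, nz, drop = FALSE], 2L, rng[nz], `/`)
  out[, !nz] <- 0  # constant features carry no information
  if (was_vector) out <- as.vector(out)
  list(values = out, stats = stats)
}

#' Feature configuration
#'
#' Bundles the tunable extraction parameters: band trimming, window centers
#' and half-width, and the image-vector side length.
#'
#' @param trim_front,trim_back bands dropped at each end (21 / 34).
#' @param window_centers band-image center wavelengths, nm.
#' @param window_half_width window half-width, nm.
#' @param image_side image-vector side length (28 -> 784 features).
#' @return list of class `feature_config`.
#' @export
feature_config <- function(trim_front = 21L, trim_back = 34L,
                           window_centers = c(1070, 1270, 1650),
                           window_half_width = 20, image_side = 28L) {
  structure(list(trim_front = as.integer(trim_front),
                 trim_back = as.integer(trim_back),
                 window_centers = window_centers,
                 window_half_width = window_half_width,
                 image_side = as.integer(image_side)),
            class = "feature_config")
}

#' Feature payloads for one calibrated ROI cube
#'
#' @param roi calibrated [hsi_cube()] (a sample's ROI).
#' @param fc a [feature_config()].
#' @return list with `spectral`, `image` and `fusion` [feature_vector()]s.
#' @export
sample_features <- function(roi, fc = feature_config()) {
  prof <- trim_bands(mean_spectrum(roi), fc$trim_front, fc$trim_back)
  spectral <- feature_vector(prof$reflectance, "spectral")
  patches <- lapply(fc$window_centers, function(ctr)
    band_window_image(roi, ctr, fc$window_half_width))
  image <- image_vector(patches, fc$image_side)
  list(spectral = spectral, image = image, fusion = fuse(spectral, image))
}

#' Feature matrices for a dataset
#'
#' @param dataset list of sample records from [generate_dataset()].
#' @param fc a [feature_config()].
#' @return list with matrices `spectral`, `image`, `fusion` (samples x dim)
#'   and vectors `ssc`, `maturity`, `sample_id`.
#' @export
dataset_features <- function(dataset, fc = feature_config()) {
  feats <- lapply(dataset, function(rec) sample_features(rec$cube, fc))
  list(spectral = do.call(rbind, lapply(feats, function(f) unclass(f$spectral))),
       image = do.call(rbind, lapply(feats, function(f) unclass(f$image))),
       fusion = do.call(rbind, lapply(feats, function(f) unclass(f$fusion))),
       ssc = vapply(dataset, `[[`, 0, "ssc"),
       maturity = vapply(dataset, `[[`, "", "maturity"),
       sample_id = vapply(dataset, `[[`, "", "sample_id"))
}
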