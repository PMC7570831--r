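#' Hyperspectral cube
#'
#' A cube is a `rows x cols x bands` numeric array with a strictly increasing
#' wavelength axis (nm) and a `kind` flag distinguishing raw sensor intensity
#' from calibrated reflectance. Pixel coordinates are 0-free R conventions:
#' 1-based `(row, col, band)` indexing, row = scan line, col = sample.
#'
#' @param values numeric 3-D array, `rows x cols x bands`.
#' @param wavelengths numeric vector of band-center wavelengths in nm,
#'   strictly increasing, one per band.
#' @param kind `"raw"` (sensor counts) or `"reflectance"` (unitless, nominally
#'   in `[0, 1]` after calibration with clamping).
#' @return An object of class `hsi_cube`.
#' @export
hsi_cube <- function(values, wavelengths, kind = c("raw", "reflectance")) {
  kind <- match.arg(kind)
  if (!is.array(values) || length(dim(values)) != 3L)
    invalid_input("`values` must be a rows x cols x bands 3-D array")
  if (!is.numeric(values)) invalid_input("`values` must be numeric")
  wavelengths <- as.numeric(wavelengths)
  if (length(wavelengths) != dim(values)[3L])
    invalid_input(sprintf("wavelength count (%d) != band count (%d)",
                          length(wavelengths), dim(values)[3L]))
  if (length(wavelengths) >= 2L && any(diff(wavelengths) <= 0))
    invalid_input("wavelengths must be strictly increasing")
  structure(list(values = values, wavelengths = wavelengths, kind = kind),
            class = "hsi_cube")
}

#' @export
dim.hsi_cube <- function(x) dim(x$values)

#' Number of spectral bands in a cube
#' @param cube an [hsi_cube()].
#' @return integer band count.
#' @export
n_bands <- function(cube) length(cube$wavelengths)

#' @export
print.hsi_cube <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<hsi_cube> %d x %d pixels, %d bands [%.1f-%.1f nm], kind=%s\n",
              d[1], d[2], d[3], min(x$wavelengths), max(x$wavelengths), x$kind))
  invisible(x)
}

#' Reference frame for reflectance calibration
#'
#' White (standard reflector) or dark (closed-shutter) calibration frame,
#' shaped like the raw cube it calibrates.
#'
#' @param values numeric 3-D array matching the raw cube, or a numeric vector
#'   of per-band intensities to be broadcast over all pixels.
#' @param role `"white"` or `"dark"`.
#' @return An object of class `reference_frame`.
#' @export
reference_frame <- function(values, role = c("white", "dark")) {
  role <- match.arg(role)
  if (is.array(values) && length(dim(values)) == 3L) {
    # full frame
  } else if (is.numeric(values) && is.null(dim(values))) {
    values <- as.numeric(values)  # per-band vector, broadcast at use
  } else {
    invalid_input("reference values must be a 3-D array or a per-band vector")
  }
  structure(list(values = values, role = role), class = "reference_frame")
}

ref_values <- function(ref, target_dim) {
  v <- if (inherits(ref, "reference_frame")) ref$values else ref
  if (is.array(v) && length(dim(v)) == 3L) {
    if (!identical(dim(v), target_dim))
      invalid_input("reference frame shape does not match cube shape")
    return(v)
  }
  if (length(v) == target_dim[3L])  # per-band scalar, broadcast
    return(aperm(array(v, dim = target_dim[c(3L, 1L, 2L)]), c(2L, 3L, 1L)))
  if (length(v) == 1L)
    return(array(v, dim = target_dim))
  invalid_input("reference vector length does not match band count")
}

#' White/dark reflectance calibration
#'
#' Converts raw intensity to reflectance via the standard line-scan formula
#' \deqn{R = (I_{raw} - I_{dark}) / (I_{white} - I_{dark})}
#' applied elementwise. References may be full frames or per-band vectors
#' (broadcast over pixels).
#'
#' @param raw an [hsi_cube()] of kind `"raw"`.
#' @param white,dark [reference_frame()]s (or arrays/per-band vectors).
#' @param clamp clip reflectance to `[0, 1]` (default `TRUE`). With clamping
#'   on, voxels where `white == dark` are set to 0; with clamping off they
#'   raise a degenerate-reference error.
#' @return An [hsi_cube()] of kind `"reflectance"`. The `fruit_mask` attribute,
#'   if present on `raw`, is carried over.
#' @export
calibrate <- function(raw, white, dark, clamp = TRUE) {
  if (!inherits(raw, "hsi_cube")) invalid_input("`raw` must be an hsi_cube")
  d <- dim(raw$values)
  w <- ref_values(white, d)
  k <- ref_values(dark, d)
  denom <- w - k
  zero <- denom == 0
  if (any(zero)) {
    if (!clamp)
      degenerate_reference("white == dark at one or more voxels")
    denom[zero] <- 1  # placeholder; result forced to 0 below
  }
  refl <- (raw$values - k) / denom
  if (any(zero)) refl[zero] <- 0
  if (clamp) refl <- pmin(pmax(refl, 0), 1)
  out <- hsi_cube(refl, raw$wavelengths, kind = "reflectance")
  attr(out, "fruit_mask") <- attr(raw, "fruit_mask")
  out
}

#' Fruit mask attached to a cube
#'
#' Phantom cubes carry their ground-truth fruit mask; for measured cubes a
#' mask can be estimated by thresholding mean reflectance against the (dark)
#' background.
#'
#' @param cube an [hsi_cube()].
#' @param threshold reflectance threshold used when no stored mask exists.
#' @return logical `rows x cols` matrix, `TRUE` on fruit pixels.
#' @export
fruit_mask <- function(cube, threshold = 0.2) {
  m <- attr(cube, "fruit_mask")
  if (!is.null(m)) return(m)
  if (cube$kind != "reflectance")
    invalid_input("mask estimation needs a reflectance cube")
  apply(cube$values, c(1L, 2L), mean) > threshold
}
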