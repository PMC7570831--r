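#' Configuration for hyperspectral peach phantoms
#'
#' A phantom emulates a pushbroom NIR acquisition of a single peach: a smooth
#' reflectance continuum carrying Gaussian absorption dips whose depth grows
#' affinely with soluble solids content (SSC), a center-weighted spatial field
#' (solids concentrate at the fruit center), a per-pixel illumination field
#' that cancels under white/dark calibration, and band-dependent Gaussian
#' noise with elevated variance in the leading/trailing bands that are trimmed
#' before analysis.
#'
#' @param n_rows,n_cols image size in pixels (defaults 636 x 838, the
#'   acquisition geometry the pipeline assumes).
#' @param n_bands number of spectral bands (default 508).
#' @param wl_start,wl_end wavelength endpoints in nm (defaults 908.1, 1735.6);
#'   band centers are uniform over the closed interval.
#' @param absorption_centers absorption band centers, nm (defaults 1190 and
#'   1450 nm: inside the high-variation 1000-1300 nm window and the water
#'   band region where H-group overtone/combination bands absorb).
#' @param absorption_sigma Gaussian width of each absorption band, nm.
#' @param absorption_depth_per_brix reflectance units of absorption depth per
#'   degree Brix (default 0.012, keeping reflectance positive up to 14.1 Brix).
#' @param absorption_efficiency_rel_sd relative SD of a per-fruit absorption
#'   efficiency factor (default 0.1): fruit differ in how strongly a degree
#'   Brix absorbs, so the mean spectrum alone does not pin down SSC exactly —
#'   the nuisance that keeps spectral-only regression off the ceiling. Set to
#'   0 for datasets whose SSC is an exact affine function of absorption depth.
#' @param spatial_gradient fraction by which SSC-driven absorption is stronger
#'   at the fruit center than at the rim, at the reference 10 degrees Brix
#'   (radial cosine taper; default 0.3). The gradient scales linearly with
#'   SSC: riper, sweeter fruit concentrate solids at the center more, so the
#'   spatial contrast itself carries SSC information independent of the
#'   per-fruit absorption efficiency.
#' @param illumination_rel_sd relative SD of the per-pixel illumination gain
#'   (default 0.05); cancels exactly under calibration.
#' @param noise_sd_core reflectance-unit noise SD in the retained bands
#'   (default 0.004).
#' @param noise_sd_edge noise SD in bands below 942 nm and above 1680 nm
#'   (default 0.02), reproducing the noisy band edges that motivate trimming.
#' @param background_reflectance flat reflectance of non-fruit pixels
#'   (default 0.05, a dark stage).
#' @param seed integer seed stored with the config (used by
#'   [generate_dataset()] to derive per-sample seeds).
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(n_rows = 636L, n_cols = 838L, n_bands = 508L,
                           wl_start = 908.1, wl_end = 1735.6,
                           absorption_centers = c(1190, 1450),
                           absorption_sigma = 45,
                           absorption_depth_per_brix = 0.012,
                           absorption_efficiency_rel_sd = 0.1,
                           spatial_gradient = 0.3,
                           illumination_rel_sd = 0.05,
                           noise_sd_core = 0.004,
                           noise_sd_edge = 0.02,
                           background_reflectance = 0.05,
                           seed = 1L) {
  if (n_bands < 2L) invalid_parameter("n_bands must be >= 2")
  if (wl_start >= wl_end) invalid_parameter("wl_start must be < wl_end")
  if (noise_sd_core < 0 || noise_sd_edge < 0 || illumination_rel_sd < 0 ||
      absorption_efficiency_rel_sd < 0)
    invalid_parameter("noise, illumination and efficiency SDs must be >= 0")
  if (any(absorption_centers < wl_start | absorption_centers > wl_end))
    invalid_parameter("absorption centers must lie within [wl_start, wl_end]")
  if (absorption_sigma <= 0) invalid_parameter("absorption_sigma must be > 0")
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 n_bands = as.integer(n_bands),
                 wl_start = wl_start, wl_end = wl_end,
                 absorption_centers = absorption_centers,
                 absorption_sigma = absorption_sigma,
                 absorption_depth_per_brix = absorption_depth_per_brix,
                 absorption_efficiency_rel_sd = absorption_efficiency_rel_sd,
                 spatial_gradient = spatial_gradient,
                 illumination_rel_sd = illumination_rel_sd,
                 noise_sd_core = noise_sd_core,
                 noise_sd_edge = noise_sd_edge,
                 background_reflectance = background_reflectance,
                 seed = as.integer(seed)),
            class = "phantom_config")
}

phantom_wavelengths <- function(config) {
  seq(config$wl_start, config$wl_end, length.out = config$n_bands)
}

# Smooth continuum with reflectance peaks near 1070 / 1270 / 1650 nm, the
# three maxima used as band-image center wavelengths downstream.
phantom_continuum <- function(wl) {
  0.45 + 0.25 * exp(-((wl - 1075) / 90)^2) +
    0.18 * exp(-((wl - 1270) / 80)^2) +
    0.20 * exp(-((wl - 1655) / 60)^2)
}

# Elliptical fruit mask plus normalized radius (0 center, 1 rim) per pixel.
phantom_geometry <- function(config) {
  r0 <- (config$n_rows + 1) / 2
  c0 <- (config$n_cols + 1) / 2
  a <- 0.42 * config$n_rows
  b <- 0.42 * config$n_cols
  rr <- outer((seq_len(config$n_rows) - r0) / a, rep(1, config$n_cols))
  cc <- outer(rep(1, config$n_rows), (seq_len(config$n_cols) - c0) / b)
  radius <- sqrt(rr^2 + cc^2)
  list(mask = radius <= 1, radius = pmin(radius, 1))
}

# Designed (noise-free) reflectance for every pixel: rows = pixels
# (column-major over row, col), cols = bands. `efficiency` is the per-fruit
# absorptivity factor (1 = nominal chemistry).
phantom_design <- function(ssc, config, efficiency = 1) {
  wl <- phantom_wavelengths(config)
  geom <- phantom_geometry(config)
  cont <- phantom_continuum(wl)
  # per-band absorption shape at unit depth; second band slightly weaker
  shape <- Reduce(`+`, Map(function(ctr, rel) {
    rel * exp(-((wl - ctr)^2) / (2 * config$absorption_sigma^2))
  }, config$absorption_centers,
  c(1, rep(0.8, length(config$absorption_centers) - 1L))))
  depth <- config$absorption_depth_per_brix * ssc * efficiency
  # radial cosine taper, 1 at the rim; center concentration grows with SSC
  # (reference 10 Brix), so the spatial contrast encodes ripeness
  gradient <- config$spatial_gradient * ssc / 10
  spatial <- 1 + gradient * cos(pi * geom$radius / 2)
  n_pix <- config$n_rows * config$n_cols
  refl <- matrix(rep(cont, each = n_pix), nrow = n_pix) -
    (depth * as.vector(spatial)) %o% shape
  refl[!as.vector(geom$mask), ] <- config$background_reflectance
  list(reflectance = refl, mask = geom$mask, wl = wl)
}

#' Generate one uncalibrated peach phantom plus calibration references
#'
#' Returns raw sensor intensities together with matching white and dark
#' reference frames, such that [calibrate()] recovers the designed reflectance
#' up to the configured noise. The raw model is
#' `raw = dark + (R + noise) * gain`, with `white = dark + gain`; the per-pixel
#' illumination field scales `gain` and therefore cancels under calibration.
#'
#' @param ssc soluble solids content of the phantom fruit, degrees Brix (> 0).
#' @param config a [phantom_config()].
#' @param seed integer seed; identical `(ssc, config, seed)` give bit-identical
#'   output.
#' @return list with elements `raw` (an [hsi_cube()], kind `"raw"`, carrying
#'   the ground-truth fruit mask as attribute `fruit_mask`), `white` and
#'   `dark` ([reference_frame()]s), and `design` (the designed reflectance
#'   cube, kind `"reflectance"`).
#' @export
generate_phantom <- function(ssc, config = phantom_config(), seed = config$seed) {
  if (!inherits(config, "phantom_config"))
    invalid_parameter("`config` must be a phantom_config")
  if (length(ssc) != 1L || !is.finite(ssc) || ssc <= 0)
    invalid_parameter("`ssc` must be a single positive value (degrees Brix)")
  set.seed(as.integer(seed))
  efficiency <- max(1 + config$absorption_efficiency_rel_sd * stats::rnorm(1),
                    0.5)
  des <- phantom_design(ssc, config, efficiency)
  n_pix <- config$n_rows * config$n_cols
  n_bands <- config$n_bands
  edge <- des$wl < 942 | des$wl > 1680
  sd_band <- ifelse(edge, config$noise_sd_edge, config$noise_sd_core)
  noise <- matrix(stats::rnorm(n_pix * n_bands), nrow = n_pix) *
    rep(sd_band, each = n_pix)
  illum <- 1 + config$illumination_rel_sd * stats::rnorm(n_pix)
  illum <- pmax(illum, 0.2)
  dark_level <- 100
  gain_band <- 3000 * (0.9 + 0.1 * cos((des$wl - 900) / 300))
  gain <- illum %o% gain_band
  raw_v <- dark_level + (des$reflectance + noise) * gain
  to_cube <- function(m, kind) {
    hsi_cube(array(m, dim = c(config$n_rows, config$n_cols, n_bands)),
             des$wl, kind = kind)
  }
  raw <- to_cube(raw_v, "raw")
  attr(raw, "fruit_mask") <- des$mask
  design <- to_cube(des$reflectance, "reflectance")
  attr(design, "fruit_mask") <- des$mask
  list(raw = raw,
       white = reference_frame(array(dark_level + gain,
                                     dim = dim(raw$values)), "white"),
       dark = reference_frame(array(dark_level, dim = dim(raw$values)), "dark"),
       design = design)
}

# Moments of N(mu, sigma^2) truncated to [a, b].
truncnorm_moments <- function(mu, sigma, a, b) {
  al <- (a - mu) / sigma
  be <- (b - mu) / sigma
  z <- stats::pnorm(be) - stats::pnorm(al)
  phi_a <- stats::dnorm(al)
  phi_b <- stats::dnorm(be)
  m <- mu + sigma * (phi_a - phi_b) / z
  v <- sigma^2 * (1 + (al * phi_a - be * phi_b) / z - ((phi_a - phi_b) / z)^2)
  c(mean = m, sd = sqrt(v))
}

# Parent (mu, sigma) such that the truncation of N(mu, sigma^2) to [a, b] has
# the requested mean and SD; the stated summary statistics describe the
# realized sample, not the untruncated parent.
solve_truncnorm <- function(mean, sd, a, b) {
  obj <- function(p) {
    mm <- truncnorm_moments(p[1L], exp(p[2L]), a, b)
    (mm[["mean"]] - mean)^2 + (mm[["sd"]] - sd)^2
  }
  fit <- stats::optim(c(mean, log(sd)), obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 5000))
  list(mu = fit$par[1L], sigma = exp(fit$par[2L]))
}

rtruncnorm <- function(n, mu, sigma, a, b) {
  u <- stats::runif(n)
  p_a <- stats::pnorm(a, mu, sigma)
  p_b <- stats::pnorm(b, mu, sigma)
  stats::qnorm(p_a + u * (p_b - p_a), mu, sigma)
}

#' Generate a phantom dataset with SSC ground truth
#'
#' SSC values are drawn from a truncated normal calibrated so the realized
#' distribution matches the requested mean/SD within the requested range, then
#' assigned to maturity strata by ascending SSC (lowest to `immature`, highest
#' to `mature`). Each record carries the calibrated ROI sub-cube of its own
#' phantom.
#'
#' @param n number of samples; must equal `sum(maturity_counts)`.
#' @param maturity_counts named integer vector with entries `immature`,
#'   `semi_mature`, `mature` (defaults 30/50/40).
#' @param ssc_mean,ssc_sd target mean and SD of the realized SSC sample,
#'   degrees Brix (defaults 9.29, 2.17).
#' @param ssc_range closed SSC range, degrees Brix (default `c(6, 14.1)`).
#' @param config a [phantom_config()].
#' @param seed integer seed for the whole dataset.
#' @param roi_size ROI side length in pixels (rows = cols) retained per
#'   sample; defaults to 200 capped at the fruit extent.
#' @return list of `sample_record` objects, each with fields `sample_id`,
#'   `cube` (calibrated reflectance ROI), `ssc`, `maturity`.
#' @export
generate_dataset <- function(n, maturity_counts = c(immature = 30L,
                                                    semi_mature = 50L,
                                                    mature = 40L),
                             ssc_mean = 9.29, ssc_sd = 2.17,
                             ssc_range = c(6, 14.1),
                             config = phantom_config(), seed = 1L,
                             roi_size = NULL) {
  if (!setequal(names(maturity_counts),
                c("immature", "semi_mature", "mature")))
    invalid_parameter("maturity_counts needs immature/semi_mature/mature")
  maturity_counts <- maturity_counts[c("immature", "semi_mature", "mature")]
  if (n != sum(maturity_counts))
    invalid_parameter("n must equal sum(maturity_counts)")
  if (ssc_range[1L] >= ssc_range[2L])
    invalid_parameter("ssc_range bounds must be ordered")
  if (ssc_mean <= ssc_range[1L] || ssc_mean >= ssc_range[2L])
    invalid_parameter("ssc_mean must lie inside ssc_range")
  set.seed(as.integer(seed))
  par <- solve_truncnorm(ssc_mean, ssc_sd, ssc_range[1L], ssc_range[2L])
  ssc <- rtruncnorm(n, par$mu, par$sigma, ssc_range[1L], ssc_range[2L])
  maturity <- rep(names(maturity_counts), times = maturity_counts)
  maturity <- maturity[rank(ssc, ties.method = "first")]
  roi_size <- roi_size %||%
    min(200L, 2L * floor(0.4 * min(config$n_rows, config$n_cols) / 2L))
  center <- c(ceiling(config$n_rows / 2), ceiling(config$n_cols / 2))
  lapply(seq_len(n), function(i) {
    s_i <- (as.integer(seed) %% 100000L) * 20011L + i
    ph <- generate_phantom(ssc[i], config, seed = s_i)
    refl <- calibrate(ph$raw, ph$white, ph$dark, clamp = TRUE)
    roi <- extract_roi(refl, center = center, size = c(roi_size, roi_size))
    structure(list(sample_id = sprintf("S%03d", i), cube = roi,
                   ssc = ssc[i], maturity = maturity[i]),
              class = "sample_record")
  })
}

#' Ground-truth table of a phantom dataset
#'
#' @param dataset list of records from [generate_dataset()].
#' @return data.frame with columns `sample_id`, `ssc_brix`, `maturity`.
#' @export
dataset_truth <- function(dataset) {
  data.frame(sample_id = vapply(dataset, `[[`, "", "sample_id"),
             ssc_brix = vapply(dataset, `[[`, 0, "ssc"),
             maturity = vapply(dataset, `[[`, "", "maturity"),
             stringsAsFactors = FALSE)
}
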