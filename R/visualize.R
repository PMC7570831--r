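# Pixel-wise SSC maps and pseudo-color rendering. Rendering is done by
# composing an RGB array directly and writing it with png::writePNG, so the
# same map and palette always produce byte-identical files (no graphics
# device involved).

MATURITY_RANGES <- list(immature = c(0, 8.5), semi_mature = c(0, 11),
                        mature = c(0, 13.2))

#' Pixel-wise SSC map container
#'
#' @param values `rows x cols` matrix of predicted SSC (degrees Brix);
#'   background pixels `NA`.
#' @param range rendering range `(min, max)` in degrees Brix; defaults to the
#'   maturity-class range (0-8.5 / 0-11 / 0-13.2).
#' @param maturity maturity label.
#' @return object of class `ssc_map`.
#' @export
ssc_map <- function(values, range = NULL, maturity = "mature") {
  if (!is.matrix(values)) invalid_input("`values` must be a matrix")
  range <- range %||% MATURITY_RANGES[[maturity]] %||% c(0, 13.2)
  if (range[1L] >= range[2L]) invalid_parameter("range min must be < max")
  structure(list(values = values, range = range, maturity = maturity),
            class = "ssc_map")
}

#' Mean predicted SSC over the fruit pixels
#' @param map an [ssc_map()].
#' @return scalar mean, background excluded.
#' @export
map_mean <- function(map) mean(map$values, na.rm = TRUE)

#' Predict SSC for every fruit pixel
#'
#' Each masked pixel's spectrum is band-trimmed, normalized with the frozen
#' training-set statistics, passed through the SAE encoder stack and the
#' random forest. Only spectral-feature models are admissible: a fusion model
#' needs a whole-fruit image vector, which is undefined per pixel.
#'
#' @param cube calibrated reflectance [hsi_cube()] (full band grid).
#' @param sae spectral-feature [sae_model][fit_sae()]; input width must equal
#'   the trimmed band count.
#' @param rf an [fit_rf()] handle trained on the SAE's deep features.
#' @param mask logical `rows x cols` fruit mask; defaults to the cube's own.
#' @param stats training-set min/max statistics from [feature_normalize()];
#'   `NULL` skips normalization (models trained on raw reflectance).
#' @param fc [feature_config()] supplying the trim counts.
#' @param maturity maturity label controlling the default rendering range.
#' @return an [ssc_map()].
#' @export
pixelwise_predict <- function(cube, sae, rf, mask = NULL, stats = NULL,
                              fc = feature_config(), maturity = "mature") {
  if (!inherits(cube, "hsi_cube")) invalid_input("`cube` must be an hsi_cube")
  mask <- mask %||% fruit_mask(cube)
  d <- dim(cube$values)
  if (!identical(dim(mask), d[1:2]))
    invalid_input("mask shape does not match cube")
  if (!any(mask)) invalid_input("mask selects no pixels")
  keep <- trim_idx(d[3L], fc$trim_front, fc$trim_back)
  if (sae$structure[1L] != length(keep))
    incompatible_model(sprintf(
      "model input dim %d != trimmed band count %d; pixel-wise maps need a spectral-feature model",
      sae$structure[1L], length(keep)))
  v <- cube$values
  dim(v) <- c(d[1L] * d[2L], d[3L])
  idx <- which(as.vector(mask))
  x <- v[idx, keep, drop = FALSE]
  if (!is.null(stats)) x <- feature_normalize(x, stats)$values
  preds <- predict(rf, deep_features(sae, x))
  out <- matrix(NA_real_, d[1L], d[2L])
  out[idx] <- preds
  ssc_map(out, maturity = maturity)
}

# 3 x 5 bitmap glyphs for colorbar tick labels.
TICK_FONT <- list(
  "0" = c("111","101","101","101","111"),
  "1" = c("010","110","010","010","111"),
  "2" = c("111","001","111","100","111"),
  "3" = c("111","001","111","001","111"),
  "4" = c("101","101","111","001","001"),
  "5" = c("111","100","111","001","111"),
  "6" = c("111","100","111","101","111"),
  "7" = c("111","001","010","010","010"),
  "8" = c("111","101","111","101","111"),
  "9" = c("111","101","111","001","111"),
  "." = c("000","000","000","000","010"),
  "-" = c("000","000","111","000","000"),
  " " = c("000","000","000","000","000"))

render_text <- function(canvas, text, row, col, scale = 2L, value = 0.15) {
  for (ch in strsplit(text, "")[[1L]]) {
    glyph <- TICK_FONT[[ch]] %||% TICK_FONT[[" "]]
    for (r in 1:5) {
      bits <- strsplit(glyph[r], "")[[1L]] == "1"
      for (c in 1:3) {
        if (!bits[c]) next
        rr <- row + (r - 1L) * scale + seq_len(scale) - 1L
        cc <- col + (c - 1L) * scale + seq_len(scale) - 1L
        rr <- rr[rr <= nrow(canvas)]
        cc <- cc[cc <= ncol(canvas)]
        canvas[rr, cc] <- value
      }
    }
    col <- col + 4L * scale
  }
  canvas
}

#' Render an SSC map as a pseudo-color PNG
#'
#' Fruit pixels are colored over `map$range` with the chosen palette;
#' background is neutral gray. A horizontal color bar with the range printed
#' at its ends ("<min> - <max>", degrees Brix) is added below the map.
#' Output is byte-deterministic for a given map and palette.
#'
#' @param map an [ssc_map()].
#' @param palette a [grDevices::hcl.colors()] palette name (default
#'   `"Viridis"`).
#' @param path output PNG path.
#' @return invisibly, a list with `path`, `label` (the color-bar annotation)
#'   and `dim` (written image height/width).
#' @export
render_pseudocolor <- function(map, palette = "Viridis", path) {
  if (!inherits(map, "ssc_map")) invalid_input("`map` must be an ssc_map")
  cols <- grDevices::hcl.colors(256L, palette)
  rgb_lut <- t(grDevices::col2rgb(cols)) / 255
  v <- map$values
  nr <- nrow(v)
  nc <- ncol(v)
  pad <- 6L
  bar_h <- 12L
  text_h <- 12L
  total_h <- nr + pad + bar_h + 2L + text_h + pad
  img <- array(0.85, dim = c(total_h, nc, 3L))  # neutral background
  scaled <- (v - map$range[1L]) / diff(map$range)
  idx_col <- pmin(pmax(floor(scaled * 255) + 1L, 1L), 256L)
  fg <- which(!is.na(v))
  for (ch in 1:3) {
    plane <- img[seq_len(nr), , ch]
    plane[fg] <- rgb_lut[idx_col[fg], ch]
    img[seq_len(nr), , ch] <- plane
  }
  # color bar spanning map$range; side padding shrinks on narrow maps
  pad_c <- min(pad, max(0L, (nc - 2L) %/% 2L))
  bar_cols <- nc - 2L * pad_c
  bar_idx <- pmin(floor(seq(0, 1, length.out = bar_cols) * 255) + 1L, 256L)
  bar_rows <- nr + pad + seq_len(bar_h)
  for (ch in 1:3)
    img[bar_rows, pad_c + seq_len(bar_cols), ch] <-
      matrix(rgb_lut[bar_idx, ch], bar_h, bar_cols, byrow = TRUE)
  fmt <- function(x) sub("\\.?0+$", "", sprintf("%.1f", x))
  label <- sprintf("%s - %s", fmt(map$range[1L]), fmt(map$range[2L]))
  text_row <- nr + pad + bar_h + 2L
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane <- render_text(plane, fmt(map$range[1L]), text_row, pad_c + 1L)
    right_w <- nchar(fmt(map$range[2L])) * 4L * 2L
    plane <- render_text(plane, fmt(map$range[2L]), text_row,
                         max(pad_c + 1L, nc - pad_c - right_w))
    img[, , ch] <- plane
  }
  ok <- tryCatch({ png::writePNG(img, path); TRUE }, error = function(e) e)
  if (!isTRUE(ok))
    io_error(sprintf("cannot write '%s': %s", path, conditionMessage(ok)))
  invisible(list(path = path, label = label, dim = c(total_h, nc)))
}
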