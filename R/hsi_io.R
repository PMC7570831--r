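# Cube I/O: ENVI header + raw binary (BSQ or BIL interleave, 64-bit IEEE
# little-endian, data type 5) and a single-file portable archive (gzip stream
# with a JSON metadata header followed by the raw doubles). No installed R
# package reads ENVI headers, so the format layer is written here.

ARCHIVE_MAGIC <- "HSICUBE1"

#' Write a hyperspectral cube
#'
#' @param cube an [hsi_cube()].
#' @param path output path. For ENVI dialects `path` receives the binary
#'   payload and `<path>.hdr` the text header; the archive dialect writes a
#'   single file.
#' @param dialect `"envi-bsq"`, `"envi-bil"` or `"archive"`.
#' @return `path`, invisibly.
#' @export
write_cube <- function(cube, path, dialect = c("envi-bsq", "envi-bil", "archive")) {
  dialect <- match.arg(dialect)
  if (!inherits(cube, "hsi_cube")) invalid_input("`cube` must be an hsi_cube")
  ok <- tryCatch({
    if (dialect == "archive") write_cube_archive(cube, path)
    else write_cube_envi(cube, path, interleave = sub("envi-", "", dialect))
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    io_error(sprintf("cannot write '%s': %s", path, conditionMessage(ok)))
  invisible(path)
}

write_cube_envi <- function(cube, path, interleave) {
  d <- dim(cube$values)
  hdr <- c(
    "ENVI",
    "description = {peachsae hyperspectral cube}",
    sprintf("samples = %d", d[2L]),
    sprintf("lines = %d", d[1L]),
    sprintf("bands = %d", d[3L]),
    "header offset = 0",
    "file type = ENVI Standard",
    "data type = 5",
    sprintf("interleave = %s", interleave),
    "byte order = 0",
    sprintf("cube kind = %s", cube$kind),
    "wavelength units = Nanometers",
    sprintf("wavelength = {%s}",
            paste(format(cube$wavelengths, digits = 15, trim = TRUE),
                  collapse = ", ")))
  writeLines(hdr, paste0(path, ".hdr"))
  # BSQ: col fastest, then row, then band; BIL: col, band, row
  perm <- if (interleave == "bsq") c(2L, 1L, 3L) else c(2L, 3L, 1L)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(aperm(cube$values, perm)), con, size = 8L,
           endian = "little")
}

write_cube_archive <- function(cube, path) {
  d <- dim(cube$values)
  meta <- jsonlite::toJSON(list(rows = d[1L], cols = d[2L], bands = d[3L],
                                kind = cube$kind,
                                wavelengths = cube$wavelengths),
                           auto_unbox = TRUE, digits = NA)
  con <- gzfile(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(ARCHIVE_MAGIC), con)
  meta_raw <- charToRaw(as.character(meta))
  writeBin(length(meta_raw), con, size = 4L, endian = "little")
  writeBin(meta_raw, con)
  writeBin(as.numeric(cube$values), con, size = 8L, endian = "little")
}

#' Read a hyperspectral cube
#'
#' Accepts either an ENVI header/binary pair (pass the binary path; the header
#' is looked up at `<path>.hdr`) or the package's portable archive. Wavelength
#' metadata must be present: a header without a `wavelength` field is a
#' format error, never silently defaulted.
#'
#' @param path file path as given to [write_cube()].
#' @return An [hsi_cube()].
#' @export
read_cube <- function(path) {
  if (!file.exists(path)) io_error(sprintf("no such file: '%s'", path))
  if (file.exists(paste0(path, ".hdr"))) return(read_cube_envi(path))
  read_cube_archive(path)
}

parse_envi_header <- function(hdr_path) {
  lines <- readLines(hdr_path, warn = FALSE)
  # join { ... } blocks that span lines, then split key = value pairs
  fields <- list()
  buf <- ""
  depth <- 0L
  for (ln in lines) {
    buf <- if (nzchar(buf)) paste(buf, ln) else ln
    depth <- depth + lengths(regmatches(ln, gregexpr("\\{", ln))) -
      lengths(regmatches(ln, gregexpr("\\}", ln)))
    if (depth > 0L) next
    if (grepl("=", buf, fixed = TRUE)) {
      key <- trimws(sub("=.*$", "", buf))
      val <- trimws(sub("^[^=]*=", "", buf))
      fields[[tolower(key)]] <- val
    }
    buf <- ""
  }
  fields
}

envi_num <- function(fields, key) {
  v <- fields[[key]]
  if (is.null(v)) format_error(sprintf("ENVI header missing '%s'", key))
  n <- suppressWarnings(as.numeric(v))
  if (is.na(n)) format_error(sprintf("ENVI header field '%s' is not numeric", key))
  n
}

read_cube_envi <- function(path) {
  fields <- parse_envi_header(paste0(path, ".hdr"))
  samples <- envi_num(fields, "samples")
  lines_n <- envi_num(fields, "lines")
  bands <- envi_num(fields, "bands")
  dtype <- envi_num(fields, "data type")
  if (dtype != 5) format_error("only ENVI data type 5 (float64) is supported")
  interleave <- tolower(fields[["interleave"]] %||% "bsq")
  if (!interleave %in% c("bsq", "bil"))
    format_error(sprintf("unsupported interleave '%s'", interleave))
  byte_order <- envi_num(fields, "byte order")
  wl_field <- fields[["wavelength"]]
  if (is.null(wl_field))
    format_error("ENVI header has no 'wavelength' field; refusing to guess")
  wl <- as.numeric(strsplit(gsub("[{}]", "", wl_field), ",")[[1L]])
  if (anyNA(wl) || length(wl) != bands)
    format_error("wavelength list does not match band count")
  n_expected <- samples * lines_n * bands
  payload_bytes <- file.info(path)$size
  if (payload_bytes != 8 * n_expected)
    format_error(sprintf(
      "payload is %d bytes but header declares %d x %d x %d float64 (%d bytes)",
      payload_bytes, lines_n, samples, bands, 8 * n_expected))
  con <- file(path, "rb")
  on.exit(close(con))
  v <- readBin(con, "numeric", n = n_expected, size = 8L,
               endian = if (byte_order == 0) "little" else "big")
  a <- if (interleave == "bsq") {
    aperm(array(v, dim = c(samples, lines_n, bands)), c(2L, 1L, 3L))
  } else {
    aperm(array(v, dim = c(samples, bands, lines_n)), c(3L, 1L, 2L))
  }
  kind <- fields[["cube kind"]] %||% "reflectance"
  hsi_cube(a, wl, kind = kind)
}

read_cube_archive <- function(path) {
  con <- gzfile(path, "rb")
  on.exit(close(con))
  magic <- tryCatch(rawToChar(readBin(con, "raw", n = nchar(ARCHIVE_MAGIC))),
                    error = function(e) "")
  if (!identical(magic, ARCHIVE_MAGIC))
    format_error(sprintf("'%s' is neither an ENVI pair nor a cube archive", path))
  meta_len <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  if (length(meta_len) != 1L || is.na(meta_len) || meta_len <= 0L)
    format_error("corrupt archive metadata length")
  meta <- jsonlite::fromJSON(rawToChar(readBin(con, "raw", n = meta_len)))
  n_expected <- meta$rows * meta$cols * meta$bands
  v <- readBin(con, "numeric", n = n_expected, size = 8L, endian = "little")
  if (length(v) != n_expected)
    format_error("archive payload shorter than declared dimensions")
  hsi_cube(array(v, dim = c(meta$rows, meta$cols, meta$bands)),
           meta$wavelengths, kind = meta$kind)
}
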