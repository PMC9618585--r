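#' Read and write ENVI hypercubes
#'
#' Classic ENVI storage: a `key = value` text header (`.hdr`) next to a raw
#' binary raster. Supported interleaves are `bil` (line, band, sample), `bsq`
#' (band, line, sample) and `bip` (band fastest); supported data types are
#' ENVI codes 2 (int16), 4 (float32), 5 (float64) and 12 (uint16). Wavelengths
#' are written at full double precision so the axis round-trips exactly, and
#' sample metadata travel in `sample id` / `class label` / `data kind` keys.
#'
#' @param cube A [hypercube].
#' @param path Base path; `write_envi()` creates `<path>.hdr` and `<path>.raw`.
#' @param interleave One of `"bil"`, `"bsq"`, `"bip"`.
#' @param data_type One of `"uint16"`, `"int16"`, `"float32"`, `"float64"`.
#'   Integer types round to the nearest integer and must fit the type's range.
#' @return `write_envi()` returns the header path invisibly; `read_envi()`
#'   returns a [hypercube].
#' @name envi
NULL

envi_types <- data.frame(
  name = c("int16", "float32", "float64", "uint16"),
  code = c(2L, 4L, 5L, 12L),
  size = c(2L, 4L, 8L, 2L),
  what = c("integer", "double", "double", "integer"),
  signed = c(TRUE, TRUE, TRUE, FALSE),
  stringsAsFactors = FALSE
)

#' @rdname envi
#' @export
write_envi <- function(cube, path, interleave = c("bil", "bsq", "bip"),
                       data_type = "float32") {
  interleave <- match.arg(interleave)
  tp <- envi_types[envi_types$name == data_type, ]
  if (nrow(tp) != 1) {
    stop_ts(sprintf("Unsupported data type \"%s\".", data_type), "tuberspec_format_error")
  }
  d <- dim(cube$data)
  # (row, col, band) -> on-disk order with the first listed dim fastest
  perm <- switch(interleave,
    bsq = c(2, 1, 3), # sample, line, band
    bil = c(2, 3, 1), # sample, band, line
    bip = c(3, 2, 1)  # band, sample, line
  )
  v <- as.vector(aperm(cube$data, perm))
  if (tp$what == "integer") {
    v <- round(v)
    lim <- if (tp$signed) c(-32768, 32767) else c(0, 65535)
    if (any(v < lim[1] | v > lim[2])) {
      stop_ts(sprintf("Values out of range for %s.", data_type), "tuberspec_format_error")
    }
    if (!tp$signed) v <- ifelse(v > 32767, v - 65536, v) # store uint16 via signed writeBin
    storage.mode(v) <- "integer"
  }
  hdr <- c(
    "ENVI",
    "description = {tuberspec hypercube}",
    sprintf("samples = %d", d[2]),
    sprintf("lines = %d", d[1]),
    sprintf("bands = %d", d[3]),
    "header offset = 0",
    "file type = ENVI Standard",
    sprintf("data type = %d", tp$code),
    sprintf("interleave = %s", interleave),
    "byte order = 0",
    "wavelength units = Nanometers",
    sprintf("wavelength = {%s}",
            paste(sprintf("%.17g", as.numeric(cube$wavelengths)), collapse = ", ")),
    sprintf("data kind = %s", cube$kind),
    sprintf("sample id = %s", cube$sample_id),
    sprintf("class label = %s", cube$class_label)
  )
  writeLines(hdr, paste0(path, ".hdr"))
  con <- file(paste0(path, ".raw"), "wb")
  on.exit(close(con))
  writeBin(v, con, size = tp$size, endian = "little")
  invisible(paste0(path, ".hdr"))
}

#' @rdname envi
#' @param header_path Path to the `.hdr` file (or the base path).
#' @export
read_envi <- function(header_path) {
  if (!grepl("\\.hdr$", header_path)) header_path <- paste0(header_path, ".hdr")
  if (!file.exists(header_path)) {
    stop_ts(sprintf("Header not found: %s", header_path), "tuberspec_format_error")
  }
  txt <- paste(readLines(header_path, warn = FALSE), collapse = "\n")
  get_field <- function(key, required = TRUE) {
    m <- regmatches(txt, regexec(paste0("(?mi)^", key, "\\s*=\\s*(\\{[^}]*\\}|[^\n]*)"),
                                 txt, perl = TRUE))[[1]]
    if (length(m) < 2) {
      if (required) {
        stop_ts(sprintf("Missing mandatory ENVI header field \"%s\".", key),
                "tuberspec_format_error")
      }
      return(NA_character_)
    }
    trimws(m[2])
  }
  samples <- as.integer(get_field("samples"))
  lines <- as.integer(get_field("lines"))
  bands <- as.integer(get_field("bands"))
  code <- as.integer(get_field("data type"))
  interleave <- tolower(get_field("interleave"))
  if (!interleave %in% c("bil", "bsq", "bip")) {
    stop_ts(sprintf("Unsupported interleave \"%s\".", interleave), "tuberspec_format_error")
  }
  tp <- envi_types[envi_types$code == code, ]
  if (nrow(tp) != 1) {
    stop_ts(sprintf("Unsupported ENVI data type code %d.", code), "tuberspec_format_error")
  }
  wl_raw <- get_field("wavelength")
  wl <- as.numeric(strsplit(gsub("[{}]", "", wl_raw), ",")[[1]])
  if (length(wl) != bands) {
    stop_ts(sprintf("Header lists %d wavelengths for %d bands.", length(wl), bands),
            "tuberspec_format_error")
  }
  raw_path <- sub("\\.hdr$", ".raw", header_path)
  n <- samples * lines * bands
  if (file.info(raw_path)$size != n * tp$size) {
    stop_ts(sprintf("Raster size (%d bytes) does not match header (%d expected).",
                    file.info(raw_path)$size, n * tp$size), "tuberspec_format_error")
  }
  con <- file(raw_path, "rb")
  on.exit(close(con))
  v <- if (tp$what == "integer") {
    readBin(con, what = "integer", n = n, size = tp$size, signed = TRUE,
            endian = "little")
  } else {
    readBin(con, what = "double", n = n, size = tp$size, endian = "little")
  }
  if (tp$name == "uint16") v <- ifelse(v < 0, v + 65536, v)
  dims <- switch(interleave,
    bsq = c(samples, lines, bands),
    bil = c(samples, bands, lines),
    bip = c(bands, samples, lines)
  )
  inv <- switch(interleave,
    bsq = c(2, 1, 3),
    bil = c(3, 1, 2),
    bip = c(3, 2, 1)
  )
  cube_arr <- aperm(array(v, dims), inv)
  kind <- get_field("data kind", required = FALSE)
  if (is.na(kind) || !kind %in% c("raw", "reflectance")) kind <- "raw"
  sid <- get_field("sample id", required = FALSE)
  if (!is.na(sid) && sid == "NA") sid <- NA_character_
  cls <- get_field("class label", required = FALSE)
  if (!is.na(cls) && !cls %in% c("cooking", "frying")) cls <- NA_character_
  hypercube(cube_arr, new_wavelength_axis(wl), kind = kind,
            sample_id = sid, class_label = cls)
}
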