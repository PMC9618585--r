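#' Hyperspectral cube container
#'
#' A hypercube is a 3-D raster indexed `(row, col, band)` holding either raw
#' camera intensities or reflectance values, together with its wavelength axis
#' and acquisition metadata. Line-scan acquisition fixes the column and band
#' counts (here typically 320 columns and 256 bands); the number of rows varies
#' with the scanned object.
#'
#' @param data Numeric 3-D array, `rows x cols x bands`.
#' @param wavelengths `wavelength_axis` (or uniform numeric vector) with one
#'   entry per band.
#' @param kind `"raw"` (camera counts) or `"reflectance"` (calibrated).
#' @param sample_id Optional sample identifier.
#' @param class_label Optional processing-aptitude label, `"cooking"` or
#'   `"frying"`.
#'
#' @return An object of class `hypercube`.
#' @export
hypercube <- function(data, wavelengths, kind = c("raw", "reflectance"),
                      sample_id = NA_character_, class_label = NA_character_) {
  kind <- match.arg(kind)
  if (!is.array(data) || length(dim(data)) != 3) {
    stop_ts("`data` must be a 3-D array (rows x cols x bands).", "tuberspec_type_error")
  }
  if (!inherits(wavelengths, "wavelength_axis")) {
    wavelengths <- new_wavelength_axis(wavelengths)
  }
  if (dim(data)[3] != length(wavelengths)) {
    stop_ts(sprintf("Band dimension (%d) does not match wavelength axis (%d).",
                    dim(data)[3], length(wavelengths)), "tuberspec_shape_error")
  }
  if (!is.na(class_label) && !class_label %in% c("cooking", "frying")) {
    stop_ts("`class_label` must be \"cooking\", \"frying\" or NA.", "tuberspec_type_error")
  }
  structure(
    list(data = data, wavelengths = wavelengths, kind = kind,
         sample_id = sample_id, class_label = class_label),
    class = "hypercube"
  )
}

#' @export
dim.hypercube <- function(x) dim(x$data)

#' @export
print.hypercube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<hypercube> %s, %d x %d pixels, %d bands (%.1f-%.1f nm)",
              x$kind, d[1], d[2], d[3], x$wavelengths[1],
              x$wavelengths[length(x$wavelengths)]))
  if (!is.na(x$sample_id)) cat(", sample", x$sample_id)
  if (!is.na(x$class_label)) cat(sprintf(" [%s]", x$class_label))
  cat("\n")
  invisible(x)
}

#' Drop the leading noisy bands of a cube
#'
#' The first bands of InGaAs line-scan spectra have a poor signal-to-noise
#' ratio; the standard workflow removes the first 30 of 256 bands, leaving 226
#' bands starting near 994 nm.
#'
#' @param cube A [hypercube].
#' @param n_drop Number of leading bands to remove (`0 <= n_drop < n_bands`).
#' @return A [hypercube] with `n_bands - n_drop` bands and a truncated axis.
#' @export
trim_leading_bands <- function(cube, n_drop = 30) {
  n_bands <- dim(cube$data)[3]
  n_drop <- as.integer(n_drop)
  if (is.na(n_drop) || n_drop < 0 || n_drop >= n_bands) {
    stop_ts(sprintf("`n_drop` must satisfy 0 <= n_drop < %d.", n_bands),
            "tuberspec_empty_result")
  }
  if (n_drop == 0) return(cube)
  keep <- (n_drop + 1):n_bands
  hypercube(cube$data[, , keep, drop = FALSE],
            new_wavelength_axis(unclass(cube$wavelengths)[keep]),
            kind = cube$kind, sample_id = cube$sample_id,
            class_label = cube$class_label)
}

# rows*cols x bands view of a cube without copying band slices one by one
cube_flat <- function(cube) {
  d <- dim(cube$data)
  matrix(cube$data, nrow = d[1] * d[2], ncol = d[3])
}

#' Mean spectrum over a foreground mask
#'
#' Per-band arithmetic mean of all masked pixels; the per-tuber observation
#' used by the mean-spectrum classification approach.
#'
#' @param cube A [hypercube].
#' @param mask Logical matrix with the cube's spatial shape; at least one
#'   `TRUE` pixel.
#' @return A one-row spectra table (see [unfold()]).
#' @export
mean_spectrum <- function(cube, mask) {
  check_mask(cube, mask)
  flat <- cube_flat(cube)
  m <- colMeans(flat[as.vector(mask), , drop = FALSE])
  spec <- matrix(m, nrow = 1)
  colnames(spec) <- format_wl(cube$wavelengths)
  tibble(
    sample_id = cube$sample_id,
    class = cube$class_label,
    row = NA_integer_, col = NA_integer_,
    spectra = spec
  )
}

check_mask <- function(cube, mask) {
  d <- dim(cube$data)
  if (!is.matrix(mask) || !identical(dim(mask), d[1:2]) || !is.logical(mask)) {
    stop_ts("`mask` must be a logical matrix with the cube's spatial shape.",
            "tuberspec_shape_error")
  }
  if (!any(mask)) {
    stop_ts("Mask selects no pixels.", "tuberspec_empty_selection")
  }
  invisible(mask)
}

format_wl <- function(w) sprintf("%.6f", as.numeric(w))
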