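#' Build a uniform wavelength axis
#'
#' Constructs the band-centre wavelength grid of a line-scan NIR camera: a
#' strictly increasing, uniformly spaced vector running from `start_nm` to
#' `end_nm` inclusive. The instrument emulated by this package covers
#' 900--1,700 nm in 256 bands, i.e. a spacing of about 3.14 nm.
#'
#' @param start_nm First band centre in nm.
#' @param end_nm Last band centre in nm; must exceed `start_nm`.
#' @param n_bands Number of bands (at least 2).
#'
#' @return A numeric vector of class `wavelength_axis` holding the band-centre
#'   wavelengths in nm.
#' @examples
#' axis <- build_wavelength_axis(900, 1700, 256)
#' round(axis_spacing(axis), 2) # ~3.14 nm
#' @export
build_wavelength_axis <- function(start_nm, end_nm, n_bands) {
  if (!is.numeric(start_nm) || !is.numeric(end_nm) || end_nm <= start_nm) {
    stop_ts("`end_nm` must be greater than `start_nm`.", "tuberspec_invalid_axis")
  }
  n_bands <- as.integer(n_bands)
  if (is.na(n_bands) || n_bands < 2) {
    stop_ts("`n_bands` must be an integer >= 2.", "tuberspec_invalid_axis")
  }
  values <- seq(start_nm, end_nm, length.out = n_bands)
  new_wavelength_axis(values)
}

new_wavelength_axis <- function(values) {
  validate_wavelength_axis(values)
  structure(as.numeric(values), class = c("wavelength_axis", "numeric"))
}

validate_wavelength_axis <- function(values) {
  if (length(values) < 2 || any(diff(values) <= 0)) {
    stop_ts("Wavelength axis must be strictly increasing with >= 2 bands.",
            "tuberspec_invalid_axis")
  }
  sp <- diff(values)
  if (max(sp) - min(sp) > 1e-9) {
    stop_ts("Wavelength axis must be uniformly spaced (tolerance 1e-9 nm).",
            "tuberspec_invalid_axis")
  }
  invisible(values)
}

#' @rdname build_wavelength_axis
#' @param axis A `wavelength_axis` (or plain numeric wavelength vector).
#' @export
axis_spacing <- function(axis) {
  (axis[length(axis)] - axis[1]) / (length(axis) - 1)
}

#' @export
print.wavelength_axis <- function(x, ...) {
  cat(sprintf("<wavelength_axis> %d bands, %.2f-%.2f nm (spacing %.4f nm)\n",
              length(x), x[1], x[length(x)], axis_spacing(x)))
  invisible(x)
}
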