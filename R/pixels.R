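#' Unfold a hypercube into a spectra table
#'
#' Flattens the masked pixels of a cube into a tibble with one row per
#' foreground pixel: identifier columns (`sample_id`, `class`), image
#' coordinates (`row`, `col`, 1-based, origin top-left) and a matrix column
#' `spectra` (`n_pixels x n_bands`, wavelengths as column names). Row order is
#' the row-major scan of the mask. [fold()] inverts the operation.
#'
#' @param cube A [hypercube].
#' @param mask Logical matrix with the cube's spatial shape; at least one
#'   `TRUE` pixel.
#' @return A tibble (`spectra` is a matrix column).
#' @examples
#' cube <- hypercube(array(1:12 / 12, c(2, 2, 3)), build_wavelength_axis(0, 2, 3),
#'                   kind = "reflectance")
#' px <- unfold(cube, matrix(TRUE, 2, 2))
#' dim(px$spectra) # 4 x 3
#' @export
unfold <- function(cube, mask) {
  check_mask(cube, mask)
  d <- dim(cube$data)
  idx <- which(mask, arr.ind = TRUE)
  ord <- order(idx[, 1], idx[, 2]) # row-major scan
  idx <- idx[ord, , drop = FALSE]
  lin <- (idx[, 2] - 1L) * d[1] + idx[, 1]
  spec <- cube_flat(cube)[lin, , drop = FALSE]
  colnames(spec) <- format_wl(cube$wavelengths)
  tibble(
    sample_id = rep(cube$sample_id, nrow(idx)),
    class = rep(cube$class_label, nrow(idx)),
    row = as.integer(idx[, 1]),
    col = as.integer(idx[, 2]),
    spectra = spec
  )
}

#' Fold per-pixel values back into an image
#'
#' Places one scalar (or label) per coordinate into a `rows x cols` image,
#' filling everything else with `background`. Used to turn pixel-wise
#' predictions back into classification maps.
#'
#' @param values Vector, one entry per coordinate row.
#' @param coords Two-column matrix or data frame of (row, col) 1-based
#'   coordinates.
#' @param source_shape Integer vector `c(rows, cols)`.
#' @param background Value used outside the coordinates (default `NA`).
#' @return A `rows x cols` matrix.
#' @export
fold <- function(values, coords, source_shape, background = NA) {
  coords <- as.matrix(coords)[, 1:2, drop = FALSE]
  storage.mode(coords) <- "integer"
  if (length(values) != nrow(coords)) {
    stop_ts("`values` and `coords` must have the same length.", "tuberspec_shape_error")
  }
  rows <- source_shape[1]; cols <- source_shape[2]
  if (nrow(coords) > 0 &&
      (any(coords[, 1] < 1L) || any(coords[, 1] > rows) ||
       any(coords[, 2] < 1L) || any(coords[, 2] > cols))) {
    stop_ts("Coordinates outside `source_shape`.", "tuberspec_bounds_error")
  }
  img <- matrix(background, rows, cols)
  img[coords] <- values
  img
}
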