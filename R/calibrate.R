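#' White/dark reference pair
#'
#' Holds the averaged white-tile and dark-current reference scans used for
#' reflectance calibration. References recorded as short line-scan cubes
#' (`lines x cols x bands`) are averaged over the scan direction to one
#' `cols x bands` array, the per-column correction standard for push-broom
#' cameras.
#'
#' @param white,dark Either a `cols x bands` matrix or a 3-D array
#'   (`lines x cols x bands`) that is averaged over its first dimension. Both
#'   must have the same shape, and the averaged white must dominate the dark
#'   everywhere.
#' @return An object of class `reference_pair` with matrices `white` and
#'   `dark` (`cols x bands`).
#' @export
reference_pair <- function(white, dark) {
  white <- average_scan(white)
  dark <- average_scan(dark)
  if (!identical(dim(white), dim(dark))) {
    stop_ts("White and dark references must share the same (cols x bands) shape.",
            "tuberspec_shape_error")
  }
  if (any(white < dark)) {
    stop_ts("Averaged white reference is below the dark reference somewhere.",
            "tuberspec_degenerate_reference")
  }
  structure(list(white = white, dark = dark), class = "reference_pair")
}

average_scan <- function(x) {
  if (inherits(x, "hypercube")) x <- x$data
  if (is.array(x) && length(dim(x)) == 3) {
    d <- dim(x)
    x <- colMeans(matrix(x, nrow = d[1]), dims = 1)
    x <- matrix(x, d[2], d[3])
  }
  if (!is.matrix(x)) {
    stop_ts("Reference must be a (cols x bands) matrix or a (lines x cols x bands) array.",
            "tuberspec_type_error")
  }
  x
}

#' Calibrate raw intensities to relative reflectance
#'
#' Converts raw camera counts to relative reflectance against white and dark
#' reference scans, per column x and band lambda:
#' \deqn{R(x,\lambda) = \frac{I(x,\lambda) - I_D(x,\lambda)}
#'                           {I_W(x,\lambda) - I_D(x,\lambda)}}
#' The transform is invariant to a common affine rescaling of I, I_D and I_W,
#' and strictly increasing in I for valid references.
#'
#' @param raw A [hypercube] of kind `"raw"`.
#' @param refs A [reference_pair] whose columns/bands match the cube.
#' @param clip If `TRUE`, clamp the result to `[0, clip_max]`. Off by default:
#'   slice reflectance mostly lies in 0--0.6 and out-of-range values are kept
#'   as evidence of noise.
#' @param clip_max Upper clamp used when `clip = TRUE`.
#' @param tol Minimum allowed white-minus-dark difference (raw counts); any
#'   position below it raises a degenerate-reference error naming the
#'   (column, wavelength) position rather than propagating NaN.
#' @return A [hypercube] of kind `"reflectance"`.
#' @export
calibrate_reflectance <- function(raw, refs, clip = FALSE, clip_max = 2, tol = 1e-6) {
  if (!inherits(raw, "hypercube") || raw$kind != "raw") {
    stop_ts("`raw` must be a hypercube of kind \"raw\".", "tuberspec_type_error")
  }
  if (!inherits(refs, "reference_pair")) refs <- reference_pair(refs$white, refs$dark)
  d <- dim(raw$data)
  if (!identical(dim(refs$white), c(d[2], d[3]))) {
    stop_ts(sprintf("References are %d cols x %d bands but the cube needs %d x %d.",
                    dim(refs$white)[1], dim(refs$white)[2], d[2], d[3]),
            "tuberspec_shape_error")
  }
  denom <- refs$white - refs$dark
  bad <- which(abs(denom) <= tol, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    wl <- as.numeric(raw$wavelengths)[bad[1, 2]]
    stop_ts(sprintf(
      "Degenerate reference: |white - dark| <= %g at column %d, band %d (%.2f nm).",
      tol, bad[1, 1], bad[1, 2], wl), "tuberspec_degenerate_reference")
  }
  flat <- cube_flat(raw) # rows*cols x bands
  rows <- d[1]
  dark_px <- refs$dark[rep(seq_len(d[2]), each = rows), , drop = FALSE]
  den_px <- denom[rep(seq_len(d[2]), each = rows), , drop = FALSE]
  refl <- (flat - dark_px) / den_px
  if (clip) refl <- pmin(pmax(refl, 0), clip_max)
  hypercube(array(refl, d), raw$wavelengths, kind = "reflectance",
            sample_id = raw$sample_id, class_label = raw$class_label)
}
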