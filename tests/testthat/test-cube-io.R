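# wavelength axis, trimming, calibration, ENVI round trips, unfold/fold

test_that("wavelength axis matches the instrument grid and validates input", {
  axis <- build_wavelength_axis(900, 1700, 256)
  expect_length(axis, 256)
  expect_equal(axis[1], 900)
  expect_equal(axis[256], 1700)
  expect_equal(round(axis_spacing(axis), 2), 3.14)
  expect_equal(axis_spacing(axis), 800 / 255)

  unit <- build_wavelength_axis(0, 10, 11)
  expect_equal(axis_spacing(unit), 1)
  expect_equal(as.numeric(build_wavelength_axis(900, 1700, 2)), c(900, 1700))

  expect_error_class(build_wavelength_axis(1700, 900, 10), "tuberspec_invalid_axis")
  expect_error_class(build_wavelength_axis(900, 1700, 1), "tuberspec_invalid_axis")
})

test_that("trimming the 30 leading bands leaves 226 bands from 994.12 nm", {
  cube <- hypercube(array(1, c(2, 2, 256)), build_wavelength_axis(900, 1700, 256),
                    kind = "reflectance")
  trimmed <- trim_leading_bands(cube, 30)
  expect_equal(dim(trimmed$data)[3], 226)
  expect_equal(length(trimmed$wavelengths), 226)
  expect_equal(round(trimmed$wavelengths[1], 2), 994.12)
  expect_equal(trimmed$wavelengths[1], 900 + 30 * 800 / 255)
  expect_equal(trimmed$wavelengths[226], 1700)

  expect_identical(trim_leading_bands(cube, 0), cube)
  expect_error_class(trim_leading_bands(cube, 256), "tuberspec_empty_result")
})

test_that("reflectance calibration satisfies the white/dark identities", {
  axis <- build_wavelength_axis(1000, 1040, 5)
  white <- matrix(100, 4, 5)
  dark <- matrix(20, 4, 5)
  refs <- reference_pair(white, dark)

  as_raw <- function(val) hypercube(array(val, c(3, 4, 5)), axis, kind = "raw")
  expect_true(all(calibrate_reflectance(as_raw(100), refs)$data == 1))
  expect_true(all(calibrate_reflectance(as_raw(20), refs)$data == 0))
  expect_true(all(calibrate_reflectance(as_raw(60), refs)$data == 0.5))
  expect_equal(calibrate_reflectance(as_raw(60), refs)$kind, "reflectance")
})

test_that("calibration is affine invariant and monotone in intensity", {
  axis <- build_wavelength_axis(1000, 1040, 5)
  set.seed(5)
  I <- array(runif(3 * 4 * 5, 30, 90), c(3, 4, 5))
  white <- matrix(runif(20, 95, 110), 4, 5)
  dark <- matrix(runif(20, 5, 15), 4, 5)
  r1 <- calibrate_reflectance(hypercube(I, axis, kind = "raw"),
                              reference_pair(white, dark))
  # common affine map a*I + b applied to image and references
  a <- 2.5; b <- 7
  r2 <- calibrate_reflectance(hypercube(a * I + b, axis, kind = "raw"),
                              reference_pair(a * white + b, a * dark + b))
  expect_equal(r2$data, r1$data, tolerance = 1e-12)

  r3 <- calibrate_reflectance(hypercube(I + 1, axis, kind = "raw"),
                              reference_pair(white, dark))
  expect_true(all(r3$data > r1$data))
})

test_that("degenerate references error with the offending position", {
  axis <- build_wavelength_axis(1000, 1040, 5)
  white <- matrix(100, 4, 5); dark <- matrix(20, 4, 5)
  white[2, 3] <- dark[2, 3]
  raw <- hypercube(array(50, c(3, 4, 5)), axis, kind = "raw")
  err <- expect_error(
    calibrate_reflectance(raw, reference_pair(white, dark)),
    class = "tuberspec_degenerate_reference")
  expect_match(conditionMessage(err), "column 2")
  expect_error_class(reference_pair(matrix(1, 4, 5), matrix(2, 4, 5)),
                     "tuberspec_degenerate_reference")
})

test_that("references recorded as line-scan cubes are averaged over the scan", {
  w_cube <- array(0, c(6, 4, 5))
  for (l in 1:6) w_cube[l, , ] <- 100 + l # varies along scan
  refs <- reference_pair(w_cube, array(10, c(6, 4, 5)))
  expect_equal(refs$white, matrix(103.5, 4, 5))
})

test_that("clipping bounds reflectance when requested", {
  axis <- build_wavelength_axis(1000, 1040, 5)
  refs <- reference_pair(matrix(100, 4, 5), matrix(20, 4, 5))
  raw <- hypercube(array(200, c(3, 4, 5)), axis, kind = "raw") # R = 2.25
  expect_equal(max(calibrate_reflectance(raw, refs, clip = TRUE)$data), 2)
  expect_gt(max(calibrate_reflectance(raw, refs)$data), 2)
})

test_that("ENVI write/read round trips bit-exactly across interleaves", {
  cube <- tiny_cube(5, 7, 6)
  for (il in c("bil", "bsq", "bip")) {
    tf <- withr::local_tempfile()
    write_envi(cube, tf, interleave = il, data_type = "float64")
    back <- read_envi(tf)
    expect_identical(back$data, cube$data)
    expect_identical(as.numeric(back$wavelengths), as.numeric(cube$wavelengths))
    expect_equal(back$kind, cube$kind)
    expect_equal(back$sample_id, cube$sample_id)
  }
})

test_that("integer ENVI types round to counts and read back unsigned", {
  cube <- tiny_cube(4, 3, 5, kind = "raw")
  cube$data <- cube$data * 20000 # exercise the uint16 range above 32767
  tf <- withr::local_tempfile()
  write_envi(cube, tf, data_type = "uint16")
  back <- read_envi(tf)
  expect_equal(back$data, round(cube$data))
  expect_true(max(back$data) > 32767)
})

test_that("malformed ENVI headers are rejected", {
  cube <- tiny_cube(3, 3, 4)
  tf <- withr::local_tempfile()
  write_envi(cube, tf)
  hdr <- readLines(paste0(tf, ".hdr"))

  # wavelength count mismatch
  bad <- sub("bands = 4", "bands = 5", hdr)
  writeLines(bad, paste0(tf, ".hdr"))
  expect_error_class(read_envi(tf), "tuberspec_format_error")

  # missing mandatory field
  writeLines(hdr[!grepl("^samples", hdr)], paste0(tf, ".hdr"))
  expect_error_class(read_envi(tf), "tuberspec_format_error")
})

test_that("unfold produces row-major pixel rows with coordinates", {
  cube <- tiny_cube(2, 2, 3)
  px <- unfold(cube, matrix(TRUE, 2, 2))
  expect_equal(dim(px$spectra), c(4L, 3L))
  expect_equal(px$row, c(1L, 1L, 2L, 2L)) # row-major scan
  expect_equal(px$col, c(1L, 2L, 1L, 2L))
  expect_equal(px$spectra[2, ], cube$data[1, 2, ], ignore_attr = TRUE)

  one <- matrix(FALSE, 2, 2); one[1, 2] <- TRUE
  px1 <- unfold(cube, one)
  expect_equal(nrow(px1), 1)
  expect_equal(c(px1$row, px1$col), c(1L, 2L))
  expect_error_class(unfold(cube, matrix(FALSE, 2, 2)), "tuberspec_empty_selection")
})

test_that("fold inverts unfold on any mask and is order invariant", {
  cube <- tiny_cube(4, 5, 3)
  set.seed(11)
  mask <- matrix(runif(20) > 0.4, 4, 5)
  mask[1, 1] <- TRUE
  px <- unfold(cube, mask)
  for (b in 1:3) {
    img <- fold(px$spectra[, b], cbind(px$row, px$col), c(4, 5), background = NA)
    expect_equal(img[mask], cube$data[, , b][mask])
    expect_true(all(is.na(img[!mask])))
    # joint permutation leaves the folded image unchanged
    perm <- sample(nrow(px))
    img2 <- fold(px$spectra[perm, b], cbind(px$row, px$col)[perm, ], c(4, 5),
                 background = NA)
    expect_identical(img, img2)
  }
  expect_equal(fold(1, cbind(1, 1), c(2, 2), background = 0),
               matrix(c(1, 0, 0, 0), 2, 2))
  expect_equal(fold(numeric(0), cbind(integer(0), integer(0)), c(2, 2),
                    background = 0), matrix(0, 2, 2))
  expect_error_class(fold(1, cbind(3, 1), c(2, 2)), "tuberspec_bounds_error")
  expect_error_class(fold(1:2, cbind(1, 1), c(2, 2)), "tuberspec_shape_error")
})

test_that("mean spectrum equals the mean of unfolded rows", {
  cube <- tiny_cube(4, 4, 6)
  mask <- matrix(c(TRUE, FALSE), 4, 4)
  ms <- mean_spectrum(cube, mask)
  px <- unfold(cube, mask)
  expect_equal(as.vector(ms$spectra), colMeans(px$spectra), ignore_attr = TRUE)

  uni <- hypercube(array(0.7, c(2, 2, 3)), build_wavelength_axis(0, 2, 3),
                   kind = "reflectance")
  expect_true(all(mean_spectrum(uni, matrix(TRUE, 2, 2))$spectra == 0.7))
  expect_error_class(mean_spectrum(cube, matrix(FALSE, 4, 4)),
                     "tuberspec_empty_selection")
})
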