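# chemistry arithmetic, slice generator, dataset generation and splits

test_that("reducing-sugar conversion follows the assay calibration line", {
  expect_equal(rs_from_absorbance(0.00385), 0)
  expect_equal(rs_from_absorbance(1.00385), 1.07893)
  expect_equal(rs_from_absorbance(0.2), (0.2 - 0.00385) * 1.07893)
  expect_equal(absorbance_from_rs(rs_from_absorbance(0.37)), 0.37,
               tolerance = 1e-12)
  expect_error_class(rs_from_absorbance(-0.1), "tuberspec_input_error")
})

test_that("the cultivar panel respects the class composition windows", {
  cv <- default_cultivars()
  expect_equal(nrow(cv), 10)
  expect_equal(sum(cv$class == "cooking"), 5)
  cook <- cv[cv$class == "cooking", ]
  fry <- cv[cv$class == "frying", ]
  expect_true(all(cook$dm_mean >= 17 & cook$dm_mean <= 19))
  expect_true(all(fry$dm_mean >= 20 & fry$dm_mean <= 23.2))
  expect_true(all(cv$rs_mean < 0.2))
})

test_that("a degenerate generator yields identical foreground spectra", {
  spec <- small_spec(noise_sd = 0, scatter_a_sd = 0, scatter_b_sd = 0,
                     stripe_sd = 0, depth_jitter_sd = 0, pixel_depth_sd = 0,
                     delta_pixel_sd = 0, delta = 0, pith_factor = 1)
  sl <- generate_slice("cooking", spec = spec, seed = 81)
  refl <- calibrate_reflectance(sl$raw, sl$refs)
  px <- unfold(refl, sl$truth_mask)
  expect_lt(max(apply(px$spectra, 2, sd)), 1e-10)
})

test_that("the pith is darker than the cortex", {
  spec <- small_spec(noise_sd = 0, scatter_a_sd = 0, scatter_b_sd = 0,
                     stripe_sd = 0, pixel_depth_sd = 0, delta_pixel_sd = 0)
  sl <- generate_slice("cooking", spec = spec, seed = 82)
  refl <- calibrate_reflectance(sl$raw, sl$refs)
  img <- intensity_image(refl)
  geo <- sl$geometry
  u <- sqrt(((row(img) - geo$center[1]) / geo$semi_axes[1])^2 +
            ((col(img) - geo$center[2]) / geo$semi_axes[2])^2)
  pith <- mean(img[u < spec$pith_frac])
  cortex <- mean(img[u >= spec$pith_frac & u <= 1])
  expect_lt(pith, cortex)
})

test_that("calibration inverts the generator construction exactly at zero noise", {
  spec <- small_spec(noise_sd = 0, scatter_a_sd = 0, scatter_b_sd = 0,
                     stripe_sd = 0, pixel_depth_sd = 0, delta_pixel_sd = 0)
  sl <- generate_slice("frying", spec = spec, seed = 83)
  refl <- calibrate_reflectance(sl$raw, sl$refs)
  expect_equal(refl$data, sl$reflectance$data, tolerance = 1e-12)
})

test_that("the frying class is brighter over the marker band", {
  spec <- small_spec(noise_sd = 0, scatter_a_sd = 0, scatter_b_sd = 0,
                     stripe_sd = 0, depth_jitter_sd = 0, pixel_depth_sd = 0,
                     delta_pixel_sd = 0)
  fry <- generate_slice("frying", spec = spec, seed = 84)
  cook <- generate_slice("cooking", spec = spec, seed = 84)
  w <- as.numeric(fry$raw$wavelengths)
  in_band <- w > 1220 & w < 1380
  mf <- mean_spectrum(calibrate_reflectance(fry$raw, fry$refs), fry$truth_mask)
  mc <- mean_spectrum(calibrate_reflectance(cook$raw, cook$refs), cook$truth_mask)
  gap <- as.vector(mf$spectra) - as.vector(mc$spectra)
  expect_true(all(gap[in_band] > 0.015))
  out_band <- w < 1150
  expect_true(all(abs(gap[out_band]) < 0.01))
})

test_that("dataset generation writes a reproducible campaign", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  spec <- small_spec()
  man1 <- generate_dataset(dir1, n_cultivars = 2, tubers_per_cultivar = 3,
                           cultivars = default_cultivars()[c(1, 6), ],
                           spec = spec, seed = 5)
  man2 <- generate_dataset(dir2, n_cultivars = 2, tubers_per_cultivar = 3,
                           cultivars = default_cultivars()[c(1, 6), ],
                           spec = spec, seed = 5)
  expect_equal(nrow(man1), 6)
  expect_equal(sum(man1$class == "cooking"), 3)
  # same seed -> byte-identical manifests
  expect_identical(readLines(file.path(dir1, "manifest.csv")),
                   readLines(file.path(dir2, "manifest.csv")))
  # files exist and a cube reads back
  expect_true(all(file.exists(file.path(dir1, man1$path_raw))))
  cube <- read_envi(file.path(dir1, man1$path_raw[1]))
  expect_equal(dim(cube$data), c(spec$shape, 256))

  # chemistry table satisfies the class windows and the assay identity
  chem <- readr::read_csv(file.path(dir1, "chemistry.csv"),
                          show_col_types = FALSE)
  expect_equal(chem$rs_pct, rs_from_absorbance(chem$absorbance),
               tolerance = 1e-12)
})

test_that("splits partition the manifest as the two designs require", {
  man <- tibble::tibble(
    sample_id = sprintf("s%02d", 1:80),
    cultivar = rep(sprintf("cv%d", 1:10), each = 8),
    class = rep(c("cooking", "frying"), each = 40)
  )
  sp <- split_dataset(man, "mean_spectra_75_25", seed = 9)
  expect_equal(sum(sp$split == "calibration"), 60)
  expect_equal(sum(sp$split == "validation"), 20)
  # stratified by class
  expect_equal(sum(sp$split == "calibration" & sp$class == "cooking"), 30)

  pw <- split_dataset(man, "pixelwise_2_1_per_cultivar", seed = 9)
  expect_equal(sum(pw$split == "calibration"), 20)
  expect_equal(sum(pw$split == "validation"), 10)
  for (cu in unique(man$cultivar)) {
    expect_equal(sum(pw$split[pw$cultivar == cu] == "calibration"), 2)
    expect_equal(sum(pw$split[pw$cultivar == cu] == "validation"), 1)
  }
  # union of assignments is the manifest, no overlap
  counts <- table(pw$split)
  expect_equal(unname(as.vector(counts[c("calibration", "validation", "unused")])),
               c(20, 10, 50))
  expect_equal(sum(counts), nrow(man))

  few <- man[1:2, ]
  expect_error_class(split_dataset(few, "pixelwise_2_1_per_cultivar"),
                     "tuberspec_parameter_error")
})

test_that("class separability scales with the offset-to-noise ratio", {
  # end-to-end at reduced size: delta = 0 is chance, large delta separates
  accs <- vapply(c(0, 0.02, 0.08), function(d) {
    dir <- withr::local_tempdir()
    generate_dataset(dir, n_cultivars = 4, tubers_per_cultivar = 5,
                     cultivars = default_cultivars()[c(1, 2, 6, 7), ],
                     spec = small_spec(delta = d), seed = 11)
    run <- run_experiment(file.path(dir, "manifest.csv"), mode = "mean",
                          chain = "SM+SNV+MC", max_lv = 5,
                          cv = list(n_splits = 10, width = 1), seed = 11)
    run$external$accuracy_pct
  }, numeric(1))
  expect_true(all(diff(accs) >= 0))
  expect_lte(accs[1], 80) # chance-ish at delta = 0 (n_val = 5)
  expect_equal(accs[3], 100)
})
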