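# Savitzky-Golay, SNV, MSC, MC operators and the named chains

test_that("SG smoothing reproduces polynomials up to the filter order exactly", {
  x <- seq(0, 10, length.out = 40)
  quad <- 2 * x^2 - 3 * x + 1
  X <- rbind(quad, rep(4, 40))
  sm <- savgol_smooth(X)
  expect_equal(sm[1, ], quad, tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(sm[2, ], rep(4, 40), tolerance = 1e-12, ignore_attr = TRUE)

  expect_error_class(savgol_smooth(X, window = 14), "tuberspec_parameter_error")
  expect_error_class(savgol_smooth(X, window = 41), "tuberspec_parameter_error")
  expect_error_class(savgol_smooth(X, window = 15, polyorder = 15),
                     "tuberspec_parameter_error")
})

test_that("SG smoothing shrinks the variance of pure noise", {
  set.seed(41)
  shrink <- replicate(200, {
    y <- rnorm(60)
    var(as.vector(savgol_smooth(matrix(y, 1)))) / var(y)
  })
  expect_lt(mean(shrink), 0.5) # 15-point quadratic filter removes most noise
  expect_true(all(shrink < 1))
})

test_that("SG derivatives are exact on low-order polynomials and scale by nm", {
  w <- seq(1000, 1100, length.out = 51) # spacing 2 nm
  lin <- 3 * w + 1
  d1 <- savgol_derivative(matrix(lin, 1), order = 1, spacing = 2)
  expect_equal(as.vector(d1), rep(3, 51), tolerance = 1e-9)

  quad <- w^2
  d2 <- savgol_derivative(matrix(quad, 1), order = 2, spacing = 2)
  expect_equal(as.vector(d2), rep(2, 51), tolerance = 1e-8)

  d1c <- savgol_derivative(matrix(rep(5, 51), 1), order = 1, spacing = 2)
  expect_equal(as.vector(d1c), rep(0, 51), tolerance = 1e-12)
})

test_that("SG operators are linear and row separable", {
  set.seed(42)
  A <- matrix(rnorm(5 * 30), 5, 30)
  B <- matrix(rnorm(5 * 30), 5, 30)
  expect_equal(savgol_smooth(2 * A + 3 * B),
               2 * savgol_smooth(A) + 3 * savgol_smooth(B), tolerance = 1e-10)
  perm <- c(3, 1, 5, 2, 4)
  expect_equal(savgol_derivative(A[perm, ], 1),
               savgol_derivative(A, 1)[perm, ], tolerance = 1e-12)
})

test_that("SNV rows have mean 0, sd 1 and the transform is idempotent", {
  X <- rbind(c(1, 2, 3), c(10, 20, 60))
  s <- snv(X)
  expect_equal(rowMeans(s), c(0, 0), tolerance = 1e-12)
  expect_equal(apply(s, 1, sd), c(1, 1), tolerance = 1e-12)
  expect_equal(snv(s), s, tolerance = 1e-12)
  # affine invariance per row, positive scale
  expect_equal(snv(3 * X + 2), s, tolerance = 1e-12)
  err <- expect_error(snv(rbind(c(1, 2, 3), c(4, 4, 4))),
                      class = "tuberspec_degenerate_spectrum")
  expect_match(conditionMessage(err), "2")
})

test_that("MSC removes per-spectrum affine scatter against the reference", {
  set.seed(43)
  ref <- as.vector(savgol_smooth(matrix(rnorm(40, 0.4, 0.1), 1)))
  expect_equal(as.vector(msc_apply(matrix(ref, 1), ref)), ref, tolerance = 1e-12)
  expect_equal(as.vector(msc_apply(matrix(2 * ref + 3, 1), ref)), ref,
               tolerance = 1e-10)

  # training set corrected against its own mean keeps column means near the ref
  Xtr <- matrix(rnorm(25 * 40, 0, 0.02), 25, 40)
  Xtr <- (1 + rnorm(25, 0, 0.2)) * (Xtr + rep(ref, each = 25)) + rnorm(25, 0, 0.1)
  corrected <- msc_apply(Xtr, msc_fit(Xtr))
  expect_equal(colMeans(corrected), msc_fit(Xtr), tolerance = 0.05)

  expect_error_class(msc_apply(matrix(1:4, 1), rep(1, 4)),
                     "tuberspec_degenerate_spectrum")
})

test_that("mean centering zeroes calibration means and transfers to test data", {
  set.seed(44)
  Xtr <- matrix(rnorm(12 * 6), 12, 6)
  mu <- mc_fit(Xtr)
  expect_equal(colMeans(mc_apply(Xtr, mu)), rep(0, 6), tolerance = 1e-12)
  expect_equal(as.vector(mc_apply(matrix(mu, 1), mu)), rep(0, 6))
  one <- matrix(rnorm(6), 1)
  expect_equal(mc_apply(one, mc_fit(one)), matrix(0, 1, 6), ignore_attr = TRUE)
  expect_error_class(mc_apply(Xtr, mu[-1]), "tuberspec_shape_error")
})

test_that("chains compose named operators in order with train-only state", {
  set.seed(45)
  Xtr <- matrix(rnorm(10 * 30, 0.4, 0.05), 10, 30)
  Xte <- matrix(rnorm(4 * 30, 0.4, 0.05), 4, 30)

  expect_equal(apply_chain(build_chain("None"), Xte), Xte, ignore_attr = TRUE)

  ft <- fit_transform_chain(build_chain("MC"), Xtr)
  expect_equal(colMeans(ft$X), rep(0, 30), tolerance = 1e-12)

  ch <- fit_chain(build_chain("SM+SNV+MC"), Xtr)
  out <- apply_chain(ch, Xte, trace = TRUE)
  expect_equal(attr(out, "trace"), c("SM", "SNV", "MC"))
  # manual composition with the same fitted state
  manual <- mc_apply(snv(savgol_smooth(Xte)), ch$state[[3]])
  expect_equal(out, manual, ignore_attr = TRUE)
  # fit-then-apply equals fit_transform on the training set
  expect_equal(apply_chain(ch, Xtr),
               fit_transform_chain(build_chain("SM+SNV+MC"), Xtr)$X)
  # applying a fitted chain twice is deterministic
  expect_identical(apply_chain(ch, Xte), apply_chain(ch, Xte))

  expect_error_class(build_chain("SM+XYZ"), "tuberspec_config_error")
  expect_error_class(apply_chain(build_chain("MSC"), Xte), "tuberspec_config_error")
})

test_that("derivative chains read band spacing from spectra-table wavelengths", {
  w <- seq(994, 1700, length.out = 30)
  lin <- matrix(3 * w + 1, 1)
  colnames(lin) <- sprintf("%.6f", w)
  tbl <- tibble::tibble(sample_id = "s", class = "cooking",
                        row = 1L, col = 1L, spectra = lin)
  ft <- fit_transform_chain(build_chain("1D"), tbl)
  expect_equal(as.vector(ft$X), rep(3, 30), tolerance = 1e-9)
})
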