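# SIMPLS PLS-DA against frozen external oracle, NIPALS cross-check, PCA

# Predicted responses from an independent PLS implementation
# (NIPALS-based, run once on the deterministic 12 x 6 fixture and frozen).
frozen_pls_responses <- list(
  `1` = c(0.714105054316, 0.570561897788, 0.235719565825, 1.020207288411,
          0.950061042883, -0.149723883717, 0.070681978730, 0.581111610372,
          0.277220200926, 0.742375305927, 1.033525785517, -0.045845846978),
  `2` = c(0.679165795229, 0.665869443789, 0.281243077933, 1.071518634496,
          1.006831130834, -0.128159149863, 0.165202481100, 0.657374630029,
          0.167824728524, 0.603394125364, 0.970572172884, -0.140837070319),
  `3` = c(0.462622053694, 0.925308720519, 0.477985666072, 1.033188164218,
          0.930418053215, -0.225366621673, 0.046425081799, 0.590968543178,
          0.180813416074, 0.671601610879, 1.020255809372, -0.114220497347)
)

test_that("SIMPLS responses match the frozen independent oracle", {
  X <- oracle_X(); cls <- oracle_class()
  for (k in 1:3) {
    m <- plsda_fit(X, n_lv = k, class = cls, positive = "one")
    pr <- predict(m, X)
    expect_equal(pr$.resp_one, frozen_pls_responses[[as.character(k)]],
                 tolerance = 1e-9)
    # the two dummy-response columns are complementary
    expect_equal(pr$.resp_one + pr$.resp_zero, rep(1, 12), tolerance = 1e-9)
  }
})

test_that("SIMPLS at full rank equals the direct least-squares solve", {
  for (seed in c(7, 8, 9)) {
    set.seed(seed)
    X <- matrix(rnorm(20 * 5), 20, 5)
    y <- rep(c("cooking", "frying"), 10)
    m <- plsda_fit(X, n_lv = 5, class = y)
    resp <- predict(m, X)$.resp_cooking
    # oracle: OLS of the centered dummy on centered X
    d <- as.numeric(y == "cooking")
    fit <- lm.fit(cbind(1, X), d)
    expect_equal(resp, as.vector(cbind(1, X) %*% fit$coefficients),
                 tolerance = 1e-6)
  }
})

test_that("NIPALS and SIMPLS agree on continuous responses", {
  X <- oracle_X(); cls <- oracle_class()
  Y <- tuberspec:::class_dummy(cls, c("one", "zero"))
  for (k in c(2, 4)) {
    simpls <- tuberspec:::simpls_core(X, Y, k)
    nip <- tuberspec:::nipals_core(X, Y, k)
    expect_equal(tuberspec:::simpls_responses(simpls, X),
                 tuberspec:::nipals_responses(nip, X), tolerance = 1e-8)
  }
})

test_that("well-separated clusters are classified perfectly with one LV", {
  sep <- separable_spectra()
  m <- plsda_fit(sep$X, n_lv = 1, class = sep$class)
  expect_equal(predict(m, sep$X)$.pred_class, sep$class)
  expect_gt(m$explained_x_variance_pct, 0)
  expect_lte(m$explained_x_variance_pct, 100)
})

test_that("class coding order does not change predictions", {
  sep <- separable_spectra(n_per_class = 10)
  m1 <- plsda_fit(sep$X, n_lv = 2, class = sep$class, positive = "cooking")
  m2 <- plsda_fit(sep$X, n_lv = 2, class = sep$class, positive = "frying")
  expect_equal(predict(m1, sep$X)$.pred_class, predict(m2, sep$X)$.pred_class)
  # relabelling classes relabels predictions symmetrically
  swapped <- ifelse(sep$class == "cooking", "frying", "cooking")
  m3 <- plsda_fit(sep$X, n_lv = 2, class = swapped, positive = "cooking")
  expect_equal(predict(m3, sep$X)$.pred_class,
               ifelse(predict(m1, sep$X)$.pred_class == "cooking",
                      "frying", "cooking"))
})

test_that("prediction is deterministic and validates shapes", {
  sep <- separable_spectra(n_per_class = 8)
  m <- plsda_fit(sep$X, n_lv = 2, class = sep$class)
  expect_identical(predict(m, sep$X), predict(m, sep$X))
  expect_equal(predict(m, sep$X[3, , drop = FALSE])$.resp_cooking,
               predict(m, sep$X)$.resp_cooking[3])
  expect_error_class(predict(m, sep$X[, 1:4]), "tuberspec_shape_error")
  expect_error_class(plsda_fit(sep$X, 2, class = rep("cooking", nrow(sep$X))),
                     "tuberspec_degenerate_labels")
  expect_error_class(plsda_fit(sep$X, n_lv = 99, class = sep$class),
                     "tuberspec_parameter_error")
})

test_that("scores are invariant to adding a constant spectrum to every sample", {
  sep <- separable_spectra(n_per_class = 8)
  m1 <- plsda_fit(sep$X, n_lv = 2, class = sep$class)
  shift <- matrix(5, nrow(sep$X), ncol(sep$X))
  m2 <- plsda_fit(sep$X + shift, n_lv = 2, class = sep$class)
  expect_equal(m1$core$scores, m2$core$scores, tolerance = 1e-9)
  p1 <- pca_fit(sep$X, 2); p2 <- pca_fit(sep$X + shift, 2)
  expect_equal(abs(p1$scores), abs(p2$scores), tolerance = 1e-9)
})

test_that("PCA explains variance correctly on structured data", {
  # rank-1 data: PC1 explains everything
  set.seed(45)
  t_ <- rnorm(20); p_ <- rnorm(6)
  X1 <- outer(t_, p_)
  pm <- pca_fit(X1, 1)
  expect_equal(pm$explained_variance_pct[1], 100, tolerance = 1e-8)

  # isotropic 2-D Gaussian: both PCs near 50%
  set.seed(46)
  X2 <- matrix(rnorm(2e4), 1e4, 2)
  pm2 <- pca_fit(X2, 2)
  expect_equal(pm2$explained_variance_pct, c(50, 50), tolerance = 0.04)
  expect_true(all(diff(pm2$explained_variance_pct) <= 1e-9))

  # orthonormal loadings and full-rank reconstruction
  set.seed(47)
  X3 <- matrix(rnorm(8 * 5), 8, 5)
  pm3 <- pca_fit(X3, 5)
  expect_equal(crossprod(pm3$loadings), diag(5), tolerance = 1e-8)
  rec <- pm3$scores %*% t(pm3$loadings) + rep(pm3$center, each = 8)
  expect_equal(rec, X3, tolerance = 1e-8, ignore_attr = TRUE)

  expect_error_class(pca_fit(X3, 9), "tuberspec_parameter_error")
})
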