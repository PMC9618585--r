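# deterministic fixtures shared across test files

# small cube with formula-based values (no RNG)
tiny_cube <- function(rows = 3, cols = 4, bands = 5, kind = "reflectance") {
  vals <- array(0, c(rows, cols, bands))
  for (b in seq_len(bands)) {
    vals[, , b] <- outer(seq_len(rows), seq_len(cols),
                         function(r, c) (r + 2 * c + 3 * b) / (rows + cols + bands))
  }
  hypercube(vals, build_wavelength_axis(1000, 1000 + 10 * (bands - 1), bands),
            kind = kind, sample_id = "tiny")
}

# 12 x 6 matrix matching the session-frozen external PLS oracle
oracle_X <- function() {
  outer(1:12, 1:6, function(i, j) sin(i * j / 3 + 0.3 * j)) + 0.05 * (1:12)
}
oracle_y <- function() c(0, 1, 0, 1, 1, 0, 0, 1, 0, 1, 1, 0)
oracle_class <- function() ifelse(oracle_y() == 1, "one", "zero")

# well-separated two-class spectra table (forced separability)
separable_spectra <- function(n_per_class = 20, n_bands = 8, gap = 5,
                              sd = 0.1, seed = 99) {
  set.seed(seed)
  X <- matrix(rnorm(2 * n_per_class * n_bands, 0, sd), ncol = n_bands)
  X[seq_len(n_per_class), 1] <- X[seq_len(n_per_class), 1] + gap
  X[-seq_len(n_per_class), 1] <- X[-seq_len(n_per_class), 1] - gap
  cls <- rep(c("cooking", "frying"), each = n_per_class)
  # interleave classes so venetian folds stay two-class
  ord <- as.vector(rbind(seq_len(n_per_class), n_per_class + seq_len(n_per_class)))
  list(X = X[ord, ], class = cls[ord])
}

# quick small slice settings used by image-level tests
small_spec <- function(...) {
  slice_spec(shape = c(64, 96), semi_axes = c(18, 24), center_jitter = 3, ...)
}

expect_error_class <- function(expr, class) {
  expect_error(expr, class = class)
}
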