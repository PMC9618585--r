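#' Spectral pre-processing operators
#'
#' Row-wise operators applied to a spectra matrix (`n_spectra x n_bands`), the
#' building blocks of the named pre-processing chains (see [build_chain()]):
#'
#' * `savgol_smooth()` — Savitzky-Golay least-squares smoothing (default
#'   15-point window, second-order polynomial). Exact on polynomials of degree
#'   up to `polyorder`; band edges are handled by the polynomial fit within the
#'   terminal window, so no bands are lost.
#' * `savgol_derivative()` — Savitzky-Golay first or second derivative with the
#'   same window/polynomial convention, scaled by `1/spacing^order` so values
#'   are per nm.
#' * `snv()` — standard normal variate: each spectrum minus its mean, divided
#'   by its standard deviation (sample convention, `n - 1`); removes
#'   multiplicative scatter per spectrum.
#' * `msc_fit()` / `msc_apply()` — multiplicative scatter correction: ordinary
#'   least squares of each spectrum on a reference spectrum
#'   (`s = a + b * ref`), returning `(s - a)/b`. The reference is the mean
#'   spectrum of the calibration set.
#' * `mc_fit()` / `mc_apply()` — mean centering: subtract the calibration-set
#'   mean spectrum; calibration column means become exactly 0.
#'
#' All operators are deterministic; SG smoothing/derivatives are linear
#' operators and everything except MSC/MC *fitting* acts on each row
#' independently.
#'
#' @param X Numeric spectra matrix (`n x n_bands`); rows are spectra.
#' @param window Odd SG window length, at most `n_bands`.
#' @param polyorder SG polynomial order, below `window`.
#' @param order Derivative order, 1 or 2 (at most `polyorder`).
#' @param spacing Band spacing in nm used to scale derivatives (default 1:
#'   per-index derivative).
#' @param reference Reference spectrum for MSC (length `n_bands`).
#' @param center Mean spectrum for MC (length `n_bands`).
#' @return A matrix of the same shape (`msc_fit()`/`mc_fit()` return the
#'   learned vector).
#' @name preprocess_ops
NULL

sg_check <- function(n_bands, window, polyorder) {
  if (window %% 2 != 1 || window > n_bands) {
    stop_ts("SG `window` must be odd and no longer than the spectrum.",
            "tuberspec_parameter_error")
  }
  if (polyorder >= window) {
    stop_ts("SG `polyorder` must be smaller than `window`.", "tuberspec_parameter_error")
  }
}

# Dense n_bands x n_bands SG operator built from signal::sgolay: interior rows
# use the central convolution kernel, terminal rows the edge rows of the
# projection matrix (polynomial fit within the first/last window).
sg_operator <- function(n_bands, window, polyorder, order = 0, spacing = 1) {
  f <- signal::sgolay(p = polyorder, n = window, m = order, ts = spacing)
  f <- unclass(f)
  k <- (window - 1) %/% 2
  s <- matrix(0, n_bands, n_bands)
  for (i in seq_len(k)) s[i, 1:window] <- f[i, ]
  for (i in (k + 1):(n_bands - k)) s[i, (i - k):(i + k)] <- f[k + 1, ]
  for (i in seq_len(k)) {
    s[n_bands - k + i, (n_bands - window + 1):n_bands] <- f[k + 1 + i, ]
  }
  s
}

#' @rdname preprocess_ops
#' @export
savgol_smooth <- function(X, window = 15, polyorder = 2) {
  X <- as_spectra_matrix(X)
  sg_check(ncol(X), window, polyorder)
  out <- X %*% t(sg_operator(ncol(X), window, polyorder))
  colnames(out) <- colnames(X)
  out
}

#' @rdname preprocess_ops
#' @export
savgol_derivative <- function(X, order, window = 15, polyorder = 2, spacing = 1) {
  X <- as_spectra_matrix(X)
  if (!order %in% c(1, 2) || order > polyorder) {
    stop_ts("Derivative `order` must be 1 or 2 and at most `polyorder`.",
            "tuberspec_parameter_error")
  }
  sg_check(ncol(X), window, polyorder)
  out <- X %*% t(sg_operator(ncol(X), window, polyorder, order = order,
                             spacing = spacing))
  colnames(out) <- colnames(X)
  out
}

#' @rdname preprocess_ops
#' @export
snv <- function(X) {
  X <- as_spectra_matrix(X)
  mu <- rowMeans(X)
  Xc <- X - mu
  s <- sqrt(rowSums(Xc^2) / (ncol(X) - 1))
  flat <- which(s <= 1e-12)
  if (length(flat) > 0) {
    stop_ts(sprintf("SNV: flat spectrum in row(s) %s.",
                    paste(utils::head(flat, 5), collapse = ", ")),
            "tuberspec_degenerate_spectrum")
  }
  out <- Xc / s
  colnames(out) <- colnames(X)
  out
}

#' @rdname preprocess_ops
#' @export
msc_fit <- function(X) {
  colMeans(as_spectra_matrix(X))
}

#' @rdname preprocess_ops
#' @export
msc_apply <- function(X, reference) {
  X <- as_spectra_matrix(X)
  if (length(reference) != ncol(X)) {
    stop_ts("MSC reference length does not match band count.", "tuberspec_shape_error")
  }
  refc <- reference - mean(reference)
  ssr <- sum(refc^2)
  if (ssr <= 1e-12) {
    stop_ts("MSC reference spectrum is constant.", "tuberspec_degenerate_spectrum")
  }
  b <- as.vector(X %*% refc) / ssr
  bad <- which(abs(b) <= 1e-12)
  if (length(bad) > 0) {
    stop_ts(sprintf("MSC: uncorrectable spectrum (slope ~ 0) in row(s) %s.",
                    paste(utils::head(bad, 5), collapse = ", ")),
            "tuberspec_uncorrectable_spectrum")
  }
  a <- rowMeans(X) - b * mean(reference)
  out <- (X - a) / b
  colnames(out) <- colnames(X)
  out
}

#' @rdname preprocess_ops
#' @export
mc_fit <- function(X) {
  colMeans(as_spectra_matrix(X))
}

#' @rdname preprocess_ops
#' @export
mc_apply <- function(X, center) {
  X <- as_spectra_matrix(X)
  if (length(center) != ncol(X)) {
    stop_ts("MC mean spectrum length does not match band count.", "tuberspec_shape_error")
  }
  out <- X - rep(center, each = nrow(X))
  colnames(out) <- colnames(X)
  out
}
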