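#' Principal component analysis of spectra
#'
#' Exploratory PCA on a spectra matrix or spectra table: the data are mean
#' centred internally, loadings are the top right-singular vectors and the
#' explained-variance percentages are the squared-singular-value shares.
#'
#' @param X Spectra matrix or spectra table (see [unfold()]).
#' @param n_pc Number of components, at most `min(n_samples - 1, n_bands)`.
#' @return An object of class `pca_model` with orthonormal `loadings`
#'   (`bands x n_pc`), `scores` (`samples x n_pc`), `explained_variance_pct`
#'   and the `center` spectrum.
#' @export
pca_fit <- function(X, n_pc = 2) {
  dat <- if (is.data.frame(X)) X else NULL
  X <- as_spectra_matrix(X)
  limit <- min(nrow(X) - 1, ncol(X))
  if (n_pc < 1 || n_pc > limit) {
    stop_ts(sprintf("`n_pc` must be between 1 and %d.", limit),
            "tuberspec_parameter_error")
  }
  center <- colMeans(X)
  Xc <- X - rep(center, each = nrow(X))
  sv <- svd(Xc, nu = n_pc, nv = n_pc)
  expl <- 100 * sv$d^2 / sum(sv$d^2)
  structure(
    list(loadings = sv$v,
         scores = sv$u %*% diag(sv$d[seq_len(n_pc)], n_pc),
         explained_variance_pct = expl[seq_len(n_pc)],
         center = center,
         wavelengths = spectra_wavelengths(X),
         class = if (!is.null(dat) && "class" %in% names(dat)) dat$class else NULL),
    class = "pca_model"
  )
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("<pca_model> %d PCs, explained variance: %s%%\n",
              ncol(x$loadings),
              paste(sprintf("%.2f", x$explained_variance_pct), collapse = ", ")))
  invisible(x)
}

#' @export
tidy.pca_model <- function(x, ...) {
  n_pc <- ncol(x$loadings)
  tibble(
    pc = rep(seq_len(n_pc), each = nrow(x$loadings)),
    wavelength = rep(x$wavelengths %||% seq_len(nrow(x$loadings)), n_pc),
    loading = as.vector(x$loadings)
  )
}

#' @export
glance.pca_model <- function(x, ...) {
  tibble(n_pc = ncol(x$loadings),
         total_explained_pct = sum(x$explained_variance_pct))
}

#' @export
autoplot.pca_model <- function(object, ...) {
  df <- tibble(
    pc1 = object$scores[, 1],
    pc2 = if (ncol(object$scores) >= 2) object$scores[, 2] else 0,
    class = object$class %||% "sample"
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$pc1, .data$pc2, colour = .data$class)) +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", object$explained_variance_pct[1]),
      y = if (ncol(object$scores) >= 2) {
        sprintf("PC2 (%.1f%%)", object$explained_variance_pct[2])
      } else "PC2",
      colour = NULL
    )
}
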