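# SIMPLS (de Jong 1993). X, Y uncentered; centering done here. Returns the
# basis needed for nested predictions with 1..ncomp latent variables.
simpls_core <- function(X, Y, ncomp) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X); p <- ncol(X); m <- ncol(Y)
  mean_x <- colMeans(X); mean_y <- colMeans(Y)
  Xc <- X - rep(mean_x, each = n)
  Yc <- Y - rep(mean_y, each = n)
  ncomp <- min(ncomp, n - 1, p)
  S <- crossprod(Xc, Yc)
  R <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp)
  Q <- matrix(0, m, ncomp); V <- matrix(0, p, ncomp)
  Tm <- matrix(0, n, ncomp)
  a_used <- 0
  for (a in seq_len(ncomp)) {
    q <- eigen(crossprod(S), symmetric = TRUE)$vectors[, 1]
    r <- S %*% q
    t_ <- Xc %*% r
    t_ <- t_ - mean(t_)
    nt <- sqrt(sum(t_^2))
    if (nt < 1e-10) break # rank exhausted
    t_ <- t_ / nt; r <- r / nt
    p_ <- crossprod(Xc, t_)
    q_ <- crossprod(Yc, t_)
    v <- p_
    if (a > 1) {
      Vp <- V[, seq_len(a - 1), drop = FALSE]
      v <- v - Vp %*% crossprod(Vp, p_)
    }
    v <- v / sqrt(sum(v^2))
    S <- S - v %*% crossprod(v, S)
    R[, a] <- r; P[, a] <- p_; Q[, a] <- q_; V[, a] <- v; Tm[, a] <- t_
    a_used <- a
  }
  if (a_used == 0) {
    stop_ts("X has no variance; cannot fit a latent-variable model.",
            "tuberspec_parameter_error")
  }
  idx <- seq_len(a_used)
  ss_x <- sum(Xc^2)
  list(R = R[, idx, drop = FALSE], P = P[, idx, drop = FALSE],
       Q = Q[, idx, drop = FALSE], scores = Tm[, idx, drop = FALSE],
       mean_x = mean_x, mean_y = mean_y, n_lv = a_used,
       explained_x_pct = cumsum(colSums(P[, idx, drop = FALSE]^2)) / ss_x * 100)
}

# continuous responses for new data with a = 1..n_lv components
simpls_responses <- function(core, X_new, n_lv = core$n_lv) {
  Xc <- as.matrix(X_new) - rep(core$mean_x, each = nrow(X_new))
  B <- core$R[, seq_len(n_lv), drop = FALSE] %*%
    t(core$Q[, seq_len(n_lv), drop = FALSE])
  Xc %*% B + rep(core$mean_y, each = nrow(X_new))
}

# NIPALS PLS2, kept as an algorithmically independent cross-check of SIMPLS.
nipals_core <- function(X, Y, ncomp, max_iter = 500, tol = 1e-12) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X)
  mean_x <- colMeans(X); mean_y <- colMeans(Y)
  E <- X - rep(mean_x, each = n)
  F_ <- Y - rep(mean_y, each = n)
  W <- matrix(0, ncol(X), ncomp); P <- matrix(0, ncol(X), ncomp)
  Q <- matrix(0, ncol(Y), ncomp)
  for (a in seq_len(ncomp)) {
    u <- F_[, which.max(colSums(F_^2))]
    if (sum(u^2) < 1e-12) { ncomp <- a - 1; break }
    repeat {
      w <- crossprod(E, u); w <- w / sqrt(sum(w^2))
      t_ <- E %*% w
      q <- crossprod(F_, t_) / sum(t_^2)
      u_new <- F_ %*% q / sum(q^2)
      if (sum((u_new - u)^2) / max(sum(u^2), 1e-30) < tol) { u <- u_new; break }
      u <- u_new
      max_iter <- max_iter - 1
      if (max_iter <= 0) break
    }
    t_ <- E %*% w
    p_ <- crossprod(E, t_) / sum(t_^2)
    q <- crossprod(F_, t_) / sum(t_^2)
    E <- E - t_ %*% t(p_)
    F_ <- F_ - t_ %*% t(q)
    W[, a] <- w; P[, a] <- p_; Q[, a] <- q
  }
  idx <- seq_len(ncomp)
  W <- W[, idx, drop = FALSE]; P <- P[, idx, drop = FALSE]; Q <- Q[, idx, drop = FALSE]
  B <- W %*% solve(crossprod(P, W), t(Q))
  list(B = B, mean_x = mean_x, mean_y = mean_y, n_lv = ncomp)
}

nipals_responses <- function(core, X_new) {
  Xc <- as.matrix(X_new) - rep(core$mean_x, each = nrow(X_new))
  Xc %*% core$B + rep(core$mean_y, each = nrow(X_new))
}

class_dummy <- function(class, classes) {
  Y <- matrix(0, length(class), length(classes),
              dimnames = list(NULL, classes))
  for (j in seq_along(classes)) Y[class == classes[j], j] <- 1
  Y
}

resolve_classes <- function(class, positive = "cooking") {
  class <- as.character(class)
  present <- unique(class[!is.na(class)])
  if (length(present) != 2) {
    stop_ts(sprintf("Exactly 2 classes required; found %d (%s).",
                    length(present), paste(present, collapse = ", ")),
            "tuberspec_degenerate_labels")
  }
  if (positive %in% present) c(positive, setdiff(present, positive)) else sort(present)
}

#' Fit a PLS-DA classifier
#'
#' Partial least squares discriminant analysis: a SIMPLS regression of the
#' two-column 0/1 class-membership dummy matrix on the spectra, with the class
#' decision taken as the class of largest predicted response (for two classes
#' this equals a 0.5 threshold on the response difference; ties go to the
#' first class). Latent variables (LVs) are linear combinations of bands that
#' maximize covariance with the class coding.
#'
#' @param data A spectra table (see [unfold()]) with a `class` column, or a
#'   bare matrix together with `class`.
#' @param n_lv Number of latent variables (>= 1).
#' @param class Class labels when `data` is a matrix.
#' @param positive Class treated as positive in downstream confusion metrics
#'   and listed first in the response columns (default `"cooking"`).
#' @return An object of class `plsda` with the SIMPLS basis, per-class
#'   regression `coefficients`, cumulative `explained_x_variance_pct` and the
#'   class order.
#' @export
plsda_fit <- function(data, n_lv, class = NULL, positive = "cooking") {
  X <- as_spectra_matrix(data)
  if (is.null(class)) {
    if (!is.data.frame(data) || !"class" %in% names(data)) {
      stop_ts("Provide `class` labels or a spectra table with a `class` column.",
              "tuberspec_type_error")
    }
    class <- data$class
  }
  class <- as.character(class)
  classes <- resolve_classes(class, positive)
  if (n_lv < 1) stop_ts("`n_lv` must be >= 1.", "tuberspec_parameter_error")
  if (n_lv > min(nrow(X) - 1, ncol(X))) {
    stop_ts(sprintf("`n_lv` must be at most min(n_samples - 1, n_bands) = %d.",
                    min(nrow(X) - 1, ncol(X))), "tuberspec_parameter_error")
  }
  core <- simpls_core(X, class_dummy(class, classes), n_lv)
  structure(
    list(core = core, classes = classes, n_lv = core$n_lv,
         coefficients = core$R %*% t(core$Q),
         explained_x_variance_pct = core$explained_x_pct[core$n_lv],
         wavelengths = spectra_wavelengths(X),
         class = class),
    class = "plsda"
  )
}

#' Predict classes for new spectra
#'
#' @param object A fitted [plsda_fit()] model.
#' @param newdata Spectra table or matrix with the model's band count.
#' @param n_lv Number of latent variables to use (defaults to the fitted
#'   number; must not exceed it).
#' @param ... Unused.
#' @return A tibble with the predicted class (`.pred_class`) and one
#'   continuous response column per class (`.resp_<class>`).
#' @export
predict.plsda <- function(object, newdata, n_lv = object$n_lv, ...) {
  X <- as_spectra_matrix(newdata)
  if (ncol(X) != nrow(object$coefficients)) {
    stop_ts(sprintf("newdata has %d bands; model expects %d.",
                    ncol(X), nrow(object$coefficients)), "tuberspec_shape_error")
  }
  if (n_lv > object$n_lv) {
    stop_ts("`n_lv` exceeds the fitted number of latent variables.",
            "tuberspec_parameter_error")
  }
  resp <- simpls_responses(object$core, X, n_lv)
  out <- tibble(.pred_class = response_labels(resp, object$classes))
  for (j in seq_along(object$classes)) {
    out[[paste0(".resp_", object$classes[j])]] <- resp[, j]
  }
  out
}

# argmax decision; exact ties resolved to the first (positive) class
response_labels <- function(resp, classes) {
  d <- resp[, 1] - resp[, 2]
  classes[ifelse(d >= 0, 1L, 2L)]
}

#' @export
print.plsda <- function(x, ...) {
  cat(sprintf("<plsda> %d LV, classes %s vs %s, %.2f%% X-variance captured\n",
              x$n_lv, x$classes[1], x$classes[2], x$explained_x_variance_pct))
  invisible(x)
}

#' @export
tidy.plsda <- function(x, ...) {
  p <- nrow(x$coefficients)
  tibble(
    wavelength = rep(x$wavelengths %||% seq_len(p), 2),
    class = rep(x$classes, each = p),
    estimate = as.vector(x$coefficients)
  )
}

#' @export
glance.plsda <- function(x, ...) {
  tibble(n_lv = x$n_lv,
         explained_x_variance_pct = x$explained_x_variance_pct,
         n = nrow(x$core$scores),
         n_bands = nrow(x$coefficients))
}

#' @export
autoplot.plsda <- function(object, ...) {
  df <- tibble(
    lv1 = object$core$scores[, 1],
    lv2 = if (object$n_lv >= 2) object$core$scores[, 2] else 0,
    class = object$class
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$lv1, .data$lv2, colour = .data$class)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "LV1 scores", y = "LV2 scores", colour = NULL)
}
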