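#' Equidistant spectral intervals
#'
#' Splits `n_bands` contiguous bands into intervals of `interval_size`
#' variables each; when the band count is not a multiple, the remainder forms
#' a final short interval so the grid still covers the whole spectrum.
#'
#' @param n_bands Total number of bands.
#' @param interval_size Variables per interval (`1 <= interval_size <=
#'   n_bands`).
#' @return A tibble with columns `interval`, `start`, `end` (1-based,
#'   inclusive band indices) and `width`; attribute `interval_size`.
#' @examples
#' nrow(make_intervals(226, 5)) # 46: 45 of width 5 plus one of width 1
#' @export
make_intervals <- function(n_bands, interval_size) {
  interval_size <- as.integer(interval_size)
  if (is.na(interval_size) || interval_size < 1 || interval_size > n_bands) {
    stop_ts("`interval_size` must be between 1 and `n_bands`.",
            "tuberspec_parameter_error")
  }
  starts <- seq(1L, n_bands, by = interval_size)
  ends <- pmin(starts + interval_size - 1L, n_bands)
  out <- tibble(interval = seq_along(starts), start = starts, end = ends,
                width = ends - starts + 1L)
  attr(out, "interval_size") <- interval_size
  out
}

#' Cross-validated root-mean-squared error of the PLS response
#'
#' RMSECV of the continuous PLS prediction of the class dummy matrix: the
#' square root of the mean squared held-out residual over all samples and both
#' dummy columns. Spectra are used as passed (apply any pre-processing chain
#' beforehand); PLS centering is re-fitted inside each fold.
#'
#' @inheritParams cross_validate
#' @return A single number.
#' @export
rmsecv <- function(data, n_lv, plan = NULL, class = NULL, positive = "cooking") {
  X <- as_spectra_matrix(data)
  if (is.null(class)) class <- data$class
  class <- as.character(class)
  classes <- resolve_classes(class, positive)
  if (is.null(plan)) plan <- venetian_blinds(nrow(X))
  eng <- cv_engine(X, class, classes, build_chain("None"), plan, n_lv)
  resp <- eng$responses[, , n_lv]
  Y <- class_dummy(class, classes)
  keep <- !is.na(resp[, 1])
  sqrt(mean((Y[keep, ] - resp[keep, ])^2))
}

#' Forward interval PLS wavelength selection
#'
#' Greedy forward selection over equidistant spectral intervals: at each step
#' the candidate interval whose inclusion gives the lowest RMSECV (with the LV
#' count re-optimized per candidate, capped at `max_lv`) joins the selection;
#' selection stops when the best candidate improves RMSECV by less than
#' `rel_tol` relative to the current value, or at `max_intervals`. Apply any
#' pre-processing chain to the spectra before selection.
#'
#' @inheritParams cross_validate
#' @param interval_size Variables per interval (typically 1 or 5).
#' @param rel_tol Minimum relative RMSECV improvement to accept a further
#'   interval (default 1e-3).
#' @param max_intervals Hard cap on the number of selected intervals.
#' @param max_lv LV cap per candidate model (default 10).
#' @return An object of class `ipls_result`: `selected` (interval indices in
#'   selection order), `rmsecv_trace`, `selected_variables` (sorted band
#'   indices), `n_lv` of the final model, `intervals`, `wavelengths`.
#' @export
forward_ipls <- function(data, interval_size, plan = NULL, class = NULL,
                         rel_tol = 1e-3, max_intervals = Inf, max_lv = 10,
                         positive = "cooking") {
  X <- as_spectra_matrix(data)
  if (nrow(X) == 0 || ncol(X) == 0) {
    stop_ts("Empty spectra matrix.", "tuberspec_parameter_error")
  }
  if (is.null(class)) class <- data$class
  class <- as.character(class)
  classes <- resolve_classes(class, positive)
  if (is.null(plan)) plan <- venetian_blinds(nrow(X))
  intervals <- make_intervals(ncol(X), interval_size)
  Y <- class_dummy(class, classes)
  none <- build_chain("None")

  # candidate LV count chosen by the usual selection criterion (mean of
  # calibration and CV class error); candidate scored by RMSECV at that LV
  score_bands <- function(bands) {
    Xb <- X[, bands, drop = FALSE]
    lv_cap <- min(max_lv, length(bands), nrow(X) - 1)
    eng <- cv_engine(Xb, class, classes, none, plan, lv_cap)
    cal <- simpls_core(Xb, Y, lv_cap)
    crit <- rmse <- numeric(lv_cap)
    for (a in seq_len(lv_cap)) {
      cal_lab <- response_labels(
        simpls_responses(cal, Xb, min(a, cal$n_lv)), classes)
      cal_err <- confusion_stats(class, cal_lab, classes[1])$class_error
      r <- eng$responses[, , a]
      keep <- !is.na(r[, 1])
      cv_lab <- response_labels(r[keep, , drop = FALSE], classes)
      cv_err <- confusion_stats(class[keep], cv_lab, classes[1])$class_error
      crit[a] <- (cal_err + cv_err) / 2
      rmse[a] <- sqrt(mean((Y[keep, ] - r[keep, ])^2))
    }
    best <- which(crit <= min(crit) + 1e-12)[1]
    list(rmsecv = rmse[best], n_lv = best)
  }

  selected <- integer(0)
  trace <- numeric(0)
  lv_trace <- integer(0)
  current <- Inf
  while (length(selected) < min(max_intervals, nrow(intervals))) {
    candidates <- setdiff(intervals$interval, selected)
    scores <- lapply(candidates, function(ci) {
      sel <- sort(c(selected, ci))
      bands <- unlist(lapply(sel, function(i) {
        intervals$start[i]:intervals$end[i]
      }))
      score_bands(bands)
    })
    rms <- vapply(scores, `[[`, numeric(1), "rmsecv")
    best_i <- which.min(rms)
    if (length(selected) > 0 &&
        (current - rms[best_i]) <= rel_tol * current) {
      break
    }
    selected <- c(selected, candidates[best_i])
    current <- rms[best_i]
    trace <- c(trace, current)
    lv_trace <- c(lv_trace, scores[[best_i]]$n_lv)
  }
  vars <- sort(unlist(lapply(selected, function(i) {
    intervals$start[i]:intervals$end[i]
  })))
  structure(
    list(selected = selected, rmsecv_trace = trace,
         selected_variables = vars, n_lv = lv_trace[length(lv_trace)],
         n_lv_trace = lv_trace, intervals = intervals,
         interval_size = attr(intervals, "interval_size"),
         wavelengths = spectra_wavelengths(X)),
    class = "ipls_result"
  )
}

#' @export
print.ipls_result <- function(x, ...) {
  cat(sprintf(
    "<ipls_result> %d interval(s) of size %d -> %d variables, final RMSECV %.4f (%d LV)\n",
    length(x$selected), x$interval_size, length(x$selected_variables),
    x$rmsecv_trace[length(x$rmsecv_trace)], x$n_lv))
  invisible(x)
}

#' @export
tidy.ipls_result <- function(x, ...) {
  w <- x$wavelengths
  tibble(
    step = seq_along(x$selected),
    interval = x$selected,
    start_band = x$intervals$start[x$selected],
    end_band = x$intervals$end[x$selected],
    start_nm = if (is.null(w)) NA_real_ else w[x$intervals$start[x$selected]],
    end_nm = if (is.null(w)) NA_real_ else w[x$intervals$end[x$selected]],
    rmsecv = x$rmsecv_trace,
    n_lv = x$n_lv_trace
  )
}

#' @export
glance.ipls_result <- function(x, ...) {
  tibble(n_intervals = length(x$selected),
         n_variables = length(x$selected_variables),
         interval_size = x$interval_size,
         final_rmsecv = x$rmsecv_trace[length(x$rmsecv_trace)],
         n_lv = x$n_lv)
}

#' @export
autoplot.ipls_result <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$step, .data$rmsecv)) +
    ggplot2::geom_step() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Forward-selection step", y = "RMSECV")
}
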