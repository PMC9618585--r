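#' Venetian-blinds cross-validation plan
#'
#' Assigns samples, in their current order, to interleaved folds: with width
#' `w`, consecutive blocks of `w` samples rotate through the `n_splits` folds
#' (`fold(i) = floor(i/w) mod n_splits`, 0-based `i`). The default 10 splits
#' of width 1 reproduce the "10 divisions, 1 sample per division" scheme.
#'
#' @param n_samples Number of samples (>= `n_splits`).
#' @param n_splits Number of folds (>= 2).
#' @param width Consecutive samples per blind.
#' @return An object of class `cv_plan` with the per-sample fold `assignment`
#'   (1-based).
#' @export
venetian_blinds <- function(n_samples, n_splits = 10, width = 1) {
  if (n_splits < 2) stop_ts("`n_splits` must be >= 2.", "tuberspec_parameter_error")
  if (n_samples < n_splits) {
    stop_ts("`n_samples` must be at least `n_splits`.", "tuberspec_parameter_error")
  }
  assignment <- ((seq_len(n_samples) - 1L) %/% width) %% n_splits + 1L
  structure(list(n_splits = as.integer(n_splits), width = as.integer(width),
                 assignment = as.integer(assignment)),
            class = "cv_plan")
}

#' @export
print.cv_plan <- function(x, ...) {
  cat(sprintf("<cv_plan> venetian blinds: %d samples, %d splits, width %d\n",
              length(x$assignment), x$n_splits, x$width))
  invisible(x)
}

# Held-out continuous responses for every LV count 1..max_lv. The chain's
# MSC reference / MC mean are re-fitted inside each fold on the training
# portion only. Returns n x 2 x max_lv array plus the folds skipped because
# the training portion had a single class.
cv_engine <- function(X, class, classes, chain, plan, max_lv) {
  n <- nrow(X)
  if (length(plan$assignment) != n) {
    stop_ts("CV plan does not match the number of samples.", "tuberspec_shape_error")
  }
  resp <- array(NA_real_, c(n, 2, max_lv))
  skipped <- integer(0)
  for (f in seq_len(plan$n_splits)) {
    test <- which(plan$assignment == f)
    if (length(test) == 0) next
    train <- setdiff(seq_len(n), test)
    if (length(unique(class[train])) < 2) {
      warn(sprintf("Fold %d has a single training class; fold skipped.", f),
           class = "tuberspec_fold_degeneracy")
      skipped <- c(skipped, f)
      next
    }
    ft <- fit_transform_chain(chain, X[train, , drop = FALSE])
    Xte <- apply_chain(ft$chain, X[test, , drop = FALSE])
    core <- simpls_core(ft$X, class_dummy(class[train], classes),
                        min(max_lv, length(train) - 1, ncol(ft$X)))
    for (a in seq_len(max_lv)) {
      resp[test, , a] <- simpls_responses(core, Xte, min(a, core$n_lv))
    }
  }
  list(responses = resp, skipped = skipped)
}

#' Cross-validate a pre-processing chain + PLS-DA model
#'
#' Runs venetian-blinds cross-validation: inside each fold the chain state
#' (MSC reference, MC mean) is re-fitted on the training portion only, a
#' PLS-DA model is fitted and the held-out samples are predicted. The
#' aggregated held-out predictions are scored with [confusion_stats()]. Folds
#' whose training portion contains one class are skipped with a warning.
#'
#' @param data Spectra table with a `class` column (or matrix plus `class`).
#' @param chain A `pp_chain` (see [build_chain()]); may be unfitted.
#' @param n_lv Number of latent variables.
#' @param plan A [venetian_blinds()] plan (defaults to 10 splits, width 1).
#' @param class Labels when `data` is a matrix.
#' @param positive Positive class (default `"cooking"`).
#' @return An object of class `plsda_cv`: `predictions` (tibble of truth,
#'   estimate and responses in sample order), `stats` (one-row
#'   [confusion_stats()] tibble), `per_class` (both class rows), `n_lv`,
#'   `plan`, `skipped_folds`.
#' @export
cross_validate <- function(data, chain, n_lv, plan = NULL, class = NULL,
                           positive = "cooking") {
  X <- as_spectra_matrix(data)
  if (is.null(class)) class <- data$class
  class <- as.character(class)
  classes <- resolve_classes(class, positive)
  if (is.null(plan)) plan <- venetian_blinds(nrow(X))
  eng <- cv_engine(X, class, classes, chain, plan, n_lv)
  resp <- eng$responses[, , n_lv]
  keep <- !is.na(resp[, 1])
  est <- rep(NA_character_, nrow(X))
  est[keep] <- response_labels(resp[keep, , drop = FALSE], classes)
  stats <- confusion_stats(class[keep], est[keep], positive = classes[1])
  structure(
    list(
      predictions = tibble(truth = class, estimate = est,
                           resp_pos = resp[, 1], resp_neg = resp[, 2],
                           fold = plan$assignment),
      stats = stats,
      per_class = per_class_stats(class[keep], est[keep], classes),
      n_lv = n_lv, plan = plan, skipped_folds = eng$skipped,
      classes = classes
    ),
    class = "plsda_cv"
  )
}

#' @export
print.plsda_cv <- function(x, ...) {
  cat(sprintf("<plsda_cv> %d LV, accuracy %.2f%%, class error %.3f\n",
              x$n_lv, x$stats$accuracy_pct, x$stats$class_error))
  invisible(x)
}

#' @export
tidy.plsda_cv <- function(x, ...) x$predictions

#' @export
glance.plsda_cv <- function(x, ...) x$stats

#' Choose the number of latent variables
#'
#' Scans 1..`max_lv` latent variables and picks the smallest count minimizing
#' the unweighted mean of the calibration class error (resubstitution on the
#' chain-fitted calibration set) and the cross-validated class error. Full
#' error curves are returned for audit.
#'
#' @inheritParams cross_validate
#' @param max_lv Largest LV count scanned.
#' @return A list with `n_lv` (the choice) and `curves` (tibble of `n_lv`,
#'   `cal_error`, `cv_error`, `score`).
#' @export
select_n_lv <- function(data, chain, max_lv, plan = NULL, class = NULL,
                        positive = "cooking") {
  X <- as_spectra_matrix(data)
  if (is.null(class)) class <- data$class
  class <- as.character(class)
  classes <- resolve_classes(class, positive)
  if (max_lv < 1) stop_ts("`max_lv` must be >= 1.", "tuberspec_parameter_error")
  max_lv <- min(max_lv, nrow(X) - 1, ncol(X))
  if (is.null(plan)) plan <- venetian_blinds(nrow(X))
  ft <- fit_transform_chain(chain, X)
  core <- simpls_core(ft$X, class_dummy(class, classes), max_lv)
  eng <- cv_engine(X, class, classes, chain, plan, max_lv)
  cal_err <- cv_err <- numeric(max_lv)
  for (a in seq_len(max_lv)) {
    cal_lab <- response_labels(simpls_responses(core, ft$X, min(a, core$n_lv)),
                               classes)
    cal_err[a] <- confusion_stats(class, cal_lab, classes[1])$class_error
    r <- eng$responses[, , a]
    keep <- !is.na(r[, 1])
    cv_lab <- response_labels(r[keep, , drop = FALSE], classes)
    cv_err[a] <- confusion_stats(class[keep], cv_lab, classes[1])$class_error
  }
  score <- (cal_err + cv_err) / 2
  best <- which(score <= min(score) + 1e-12)[1] # tie -> smallest LV count
  list(n_lv = as.integer(best),
       curves = tibble(n_lv = seq_len(max_lv), cal_error = cal_err,
                       cv_error = cv_err, score = score))
}

#' Binary confusion-matrix statistics
#'
#' Counts and derived metrics of a binary classification:
#' sensitivity = TP/(TP+FN), specificity = TN/(TN+FP),
#' class error = 1 - (sensitivity + specificity)/2 and
#' accuracy (%) = 100 (TP+TN)/(TP+TN+FP+FN).
#'
#' @param truth,estimate Equal-length label vectors.
#' @param positive Label counted as positive.
#' @return One-row tibble with `tp`, `tn`, `fp`, `fn`, `sensitivity`,
#'   `specificity`, `class_error`, `accuracy_pct`.
#' @examples
#' confusion_stats(c("a", "a", "b", "b"), c("a", "a", "b", "b"), positive = "a")
#' @export
confusion_stats <- function(truth, estimate, positive) {
  if (length(truth) == 0 || length(truth) != length(estimate)) {
    stop_ts("`truth` and `estimate` must be non-empty and of equal length.",
            "tuberspec_parameter_error")
  }
  pos_t <- truth == positive
  pos_e <- estimate == positive
  tp <- sum(pos_t & pos_e); fn <- sum(pos_t & !pos_e)
  tn <- sum(!pos_t & !pos_e); fp <- sum(!pos_t & pos_e)
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  tibble(
    tp = tp, tn = tn, fp = fp, fn = fn,
    sensitivity = sens, specificity = spec,
    class_error = class_error(sens, spec),
    accuracy_pct = 100 * (tp + tn) / (tp + tn + fp + fn)
  )
}

#' @rdname confusion_stats
#' @param sensitivity,specificity Rates in `[0, 1]`; `class_error()` computes
#'   `1 - (sensitivity + specificity)/2` directly from them.
#' @export
class_error <- function(sensitivity, specificity) {
  1 - (sensitivity + specificity) / 2
}

# both class rows (metrics mirror across classes in the binary case)
per_class_stats <- function(truth, estimate, classes) {
  dplyr::bind_rows(lapply(classes, function(cl) {
    dplyr::mutate(confusion_stats(truth, estimate, cl), class = cl,
                  .before = 1)
  }))
}
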