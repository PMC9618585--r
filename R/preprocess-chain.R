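#' Named pre-processing chains
#'
#' A chain is an ordered list of spectral operators identified by the labels
#' used throughout this package's comparison tables: `SM` (Savitzky-Golay
#' smoothing), `SNV`, `MSC`, `1D`/`2D` (SG derivatives), `MC` (mean
#' centering), joined by `+`, e.g. `"SM+SNV+MC"`; `"None"` is the identity.
#' Chains separate *fitting* (learning the MSC reference and MC mean spectrum
#' from calibration data, in chain order) from *application* (deterministic
#' transform of any data with the learned state), so validation data are never
#' allowed to influence the transform.
#'
#' @param steps A `+`-joined label string (or character vector of step names).
#' @param window,polyorder SG filter settings shared by `SM`/`1D`/`2D`.
#' @param spacing Band spacing in nm for derivative scaling; when fitting from
#'   a spectra table the spacing is taken from the wavelengths stored in the
#'   matrix column, so set this only for bare matrices.
#' @param chain A `pp_chain` object.
#' @param X Spectra matrix or spectra table.
#' @param trace If `TRUE`, attach the ordered vector of applied operator names
#'   as attribute `"trace"` of the result.
#'
#' @return `build_chain()` an unfitted `pp_chain`; `fit_chain()` a fitted
#'   `pp_chain`; `apply_chain()` the transformed spectra matrix;
#'   `fit_transform_chain()` a list with elements `chain` and `X`.
#' @examples
#' ch <- build_chain("SM+SNV+MC")
#' @export
build_chain <- function(steps, window = 15, polyorder = 2, spacing = NULL) {
  if (is.character(steps) && length(steps) == 1) {
    steps <- if (tolower(steps) == "none") character(0) else strsplit(steps, "\\+")[[1]]
  }
  steps <- toupper(trimws(steps))
  known <- c("SM", "SNV", "MSC", "1D", "2D", "MC")
  bad <- setdiff(steps, known)
  if (length(bad) > 0) {
    stop_ts(sprintf("Unknown pre-processing step(s): %s.", paste(bad, collapse = ", ")),
            "tuberspec_config_error")
  }
  structure(
    list(steps = steps, window = window, polyorder = polyorder,
         spacing = spacing, state = NULL),
    class = "pp_chain"
  )
}

#' @export
print.pp_chain <- function(x, ...) {
  lab <- if (length(x$steps) == 0) "None" else paste(x$steps, collapse = "+")
  cat(sprintf("<pp_chain> %s (%s)\n", lab,
              if (is.null(x$state)) "unfitted" else "fitted"))
  invisible(x)
}

#' @rdname build_chain
#' @export
chain_label <- function(chain) {
  if (length(chain$steps) == 0) "None" else paste(chain$steps, collapse = "+")
}

chain_spacing <- function(chain, X) {
  if (!is.null(chain$spacing)) return(chain$spacing)
  w <- spectra_wavelengths(X)
  if (!is.null(w) && length(w) >= 2) (w[length(w)] - w[1]) / (length(w) - 1) else 1
}

#' @rdname build_chain
#' @export
fit_chain <- function(chain, X) {
  fit_transform_chain(chain, X)$chain
}

#' @rdname build_chain
#' @export
fit_transform_chain <- function(chain, X) {
  sp <- chain_spacing(chain, X)
  X <- as_spectra_matrix(X)
  state <- vector("list", length(chain$steps))
  for (i in seq_along(chain$steps)) {
    step <- chain$steps[i]
    if (step == "MSC") {
      state[[i]] <- msc_fit(X)
    } else if (step == "MC") {
      state[[i]] <- mc_fit(X)
    }
    X <- apply_step(step, X, state[[i]], chain, sp)
  }
  chain$state <- state
  chain$spacing_used <- sp
  list(chain = chain, X = X)
}

#' @rdname build_chain
#' @export
apply_chain <- function(chain, X, trace = FALSE) {
  needs_state <- any(chain$steps %in% c("MSC", "MC"))
  if (needs_state && is.null(chain$state)) {
    stop_ts("Chain contains MSC/MC but has not been fitted; call fit_chain() first.",
            "tuberspec_config_error")
  }
  sp <- chain$spacing_used %||% chain_spacing(chain, X)
  X <- as_spectra_matrix(X)
  for (i in seq_along(chain$steps)) {
    X <- apply_step(chain$steps[i], X, chain$state[[i]], chain, sp)
  }
  if (trace) attr(X, "trace") <- chain$steps
  X
}

apply_step <- function(step, X, state, chain, spacing) {
  switch(step,
    SM = savgol_smooth(X, window = chain$window, polyorder = chain$polyorder),
    SNV = snv(X),
    MSC = msc_apply(X, state),
    `1D` = savgol_derivative(X, 1, window = chain$window,
                             polyorder = chain$polyorder, spacing = spacing),
    `2D` = savgol_derivative(X, 2, window = chain$window,
                             polyorder = chain$polyorder, spacing = spacing),
    MC = mc_apply(X, state)
  )
}

#' The ten benchmark pre-processing chains
#'
#' The pre-processing combinations compared by the pipeline's model tables.
#'
#' @return Character vector of chain labels.
#' @export
paper_chains <- function() {
  c("None", "MC", "SM+SNV+MC", "SM+MSC+MC", "1D+MC", "2D+MC",
    "1D+SNV+MC", "1D+MSC+MC", "2D+SNV+MC", "2D+MSC+MC")
}
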