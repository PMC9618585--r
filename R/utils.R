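# shared internal helpers

stop_ts <- function(msg, class, ...) {
  rlang::abort(msg, class = c(class, "tuberspec_error"), ...)
}

# matrix of spectra from either a bare matrix or a spectra table
as_spectra_matrix <- function(x) {
  if (is.matrix(x)) return(x)
  if (is.data.frame(x) && "spectra" %in% names(x)) return(x$spectra)
  stop_ts("`x` must be a spectra matrix or a spectra table with a `spectra` column.",
          "tuberspec_type_error")
}

# wavelengths attached as colnames of a spectra matrix, or NULL
spectra_wavelengths <- function(x) {
  m <- as_spectra_matrix(x)
  cn <- colnames(m)
  if (is.null(cn)) return(NULL)
  w <- suppressWarnings(as.numeric(cn))
  if (anyNA(w)) NULL else w
}

`%||%` <- function(a, b) if (is.null(a)) b else a
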