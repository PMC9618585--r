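#' Pixel-wise classification map
#'
#' Codes each foreground pixel of a single-slice prediction against the
#' slice's true class: on a positive-class (cooking) slice pixels are TP when
#' predicted positive and FN otherwise; on a negative-class (frying) slice
#' they are TN when predicted negative and FP otherwise. Aggregating the
#' counts over all validation slices reproduces the validation confusion
#' matrix exactly.
#'
#' @param pred_labels Character vector of per-pixel predicted classes.
#' @param true_label The slice's single true class.
#' @param coords Two-column (row, col) coordinates, as produced by [unfold()].
#' @param shape `c(rows, cols)` of the source image.
#' @param positive Positive class (default `"cooking"`).
#' @param sample_id Identifier carried into the result.
#' @return An object of class `category_image`: integer matrix `data` with
#'   codes 0 = background, 1 = TP, 2 = TN, 3 = FP, 4 = FN; named `counts`;
#'   `sample_id`.
#' @export
categorize <- function(pred_labels, true_label, coords, shape,
                       positive = "cooking", sample_id = NA_character_) {
  coords <- as.matrix(coords)[, 1:2, drop = FALSE]
  if (length(pred_labels) != nrow(coords)) {
    stop_ts("`pred_labels` and `coords` lengths differ.", "tuberspec_shape_error")
  }
  pred_pos <- pred_labels == positive
  codes <- if (true_label == positive) {
    ifelse(pred_pos, 1L, 4L) # TP / FN
  } else {
    ifelse(pred_pos, 3L, 2L) # FP / TN
  }
  img <- fold(codes, coords, shape, background = 0L)
  counts <- c(background = sum(img == 0L), tp = sum(img == 1L),
              tn = sum(img == 2L), fp = sum(img == 3L), fn = sum(img == 4L))
  structure(list(data = img, counts = counts, sample_id = sample_id,
                 true_label = true_label),
            class = "category_image")
}

#' @export
print.category_image <- function(x, ...) {
  cat(sprintf("<category_image> %s (%s): TP %d, TN %d, FP %d, FN %d\n",
              x$sample_id, x$true_label, x$counts["tp"], x$counts["tn"],
              x$counts["fp"], x$counts["fn"]))
  invisible(x)
}

#' Default classification-map palette
#'
#' TP dark green, TN dark blue, FP light green, FN yellow, black background.
#'
#' @return Named list of RGB triplets in `[0, 1]`.
#' @export
map_palette <- function() {
  list(
    background = c(0, 0, 0),
    tp = c(0.00, 0.45, 0.10),
    tn = c(0.05, 0.15, 0.55),
    fp = c(0.55, 0.85, 0.45),
    fn = c(0.95, 0.90, 0.20)
  )
}

#' Render a classification map to a PNG file
#'
#' Writes a deterministic RGB PNG of the category image; below the map a
#' legend strip shows one swatch per non-background code (TP, TN, FP, FN, in
#' that order). Two renders of the same input are byte-identical.
#'
#' @param cimg A [categorize()] result.
#' @param path Output PNG path.
#' @param palette Named list of RGB triplets for codes `background`, `tp`,
#'   `tn`, `fp`, `fn` (see [map_palette()]).
#' @param legend Append the legend strip (default `TRUE`).
#' @return The path, invisibly.
#' @export
render_map <- function(cimg, path, palette = map_palette(), legend = TRUE) {
  code_names <- c("background", "tp", "tn", "fp", "fn")
  missing <- setdiff(code_names, names(palette))
  if (length(missing) > 0) {
    stop_ts(sprintf("Palette lacks color(s) for: %s.", paste(missing, collapse = ", ")),
            "tuberspec_config_error")
  }
  img <- cimg$data
  if (!all(img %in% 0:4)) {
    stop_ts("Category image contains unknown codes.", "tuberspec_config_error")
  }
  lut <- do.call(rbind, palette[code_names]) # 5 x 3
  h <- nrow(img); w <- ncol(img)
  rgb <- array(0, c(h, w, 3))
  for (ch in 1:3) rgb[, , ch] <- matrix(lut[img + 1L, ch], h, w)
  if (legend) {
    strip_h <- max(6L, h %/% 12)
    sw <- w %/% 4
    strip <- array(0, c(strip_h, w, 3))
    for (k in 1:4) {
      cols <- ((k - 1) * sw + 1):(if (k == 4) w else k * sw)
      for (ch in 1:3) strip[, cols, ch] <- lut[k + 1L, ch]
    }
    pad <- array(0, c(2L, w, 3))
    rgb <- abind3(rgb, pad, strip)
  }
  png::writePNG(rgb, path)
  invisible(path)
}

# row-bind 3-channel images (avoids an abind dependency)
abind3 <- function(...) {
  parts <- list(...)
  h <- sum(vapply(parts, nrow, integer(1)))
  w <- ncol(parts[[1]])
  out <- array(0, c(h, w, 3))
  at <- 1L
  for (p in parts) {
    out[at:(at + nrow(p) - 1L), , ] <- p
    at <- at + nrow(p)
  }
  out
}

#' @export
tidy.category_image <- function(x, ...) {
  tibble(sample_id = x$sample_id, true_label = x$true_label,
         code = names(x$counts), count = as.integer(x$counts))
}

#' @export
autoplot.category_image <- function(object, ...) {
  code_names <- c("background", "TP", "TN", "FP", "FN")
  df <- tibble(
    row = rep(seq_len(nrow(object$data)), ncol(object$data)),
    col = rep(seq_len(ncol(object$data)), each = nrow(object$data)),
    code = factor(code_names[as.vector(object$data) + 1L], levels = code_names)
  )
  pal <- vapply(map_palette(), function(p) grDevices::rgb(p[1], p[2], p[3]),
                character(1))
  names(pal) <- code_names
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row, fill = .data$code)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = pal) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, fill = NULL,
                  title = object$sample_id)
}
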