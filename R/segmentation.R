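#' Segment a potato slice from the dark background
#'
#' Binarizes a reflectance cube into a single-slice foreground mask in three
#' steps: project the cube to a per-pixel mean-reflectance image
#' ([intensity_image()]), threshold it by Otsu's criterion over a 256-bin
#' histogram of the image range ([otsu_threshold()]), then clean the binary
#' image morphologically and keep the single largest 8-connected component
#' ([clean_mask()]). The local-contrast superpixel stage sometimes used
#' upstream of Otsu is deliberately not reproduced; on a dark sample holder
#' the mean-band projection already separates slice from background.
#'
#' @param cube A reflectance [hypercube].
#' @param min_object_px Components smaller than this are discarded before the
#'   largest is kept (default 50 px).
#' @param closing_radius Disc radius (px) of the morphological closing
#'   (default 2).
#' @return `segment_slice()` returns a logical mask matrix with attribute
#'   `n_foreground`.
#' @export
segment_slice <- function(cube, min_object_px = 50, closing_radius = 2) {
  img <- intensity_image(cube)
  thr <- otsu_threshold(img)
  clean_mask(img > thr, min_object_px = min_object_px,
             closing_radius = closing_radius)
}

#' @rdname segment_slice
#' @export
intensity_image <- function(cube) {
  d <- dim(cube$data)
  matrix(rowMeans(cube_flat(cube)), d[1], d[2])
}

#' @rdname segment_slice
#' @param image Numeric matrix with at least two distinct values.
#' @export
otsu_threshold <- function(image) {
  rng <- range(image)
  if (diff(rng) == 0) {
    stop_ts("Cannot threshold a constant image.", "tuberspec_degenerate_histogram")
  }
  EBImage::otsu(image, range = rng, levels = 256)
}

#' @rdname segment_slice
#' @param mask Logical matrix.
#' @export
clean_mask <- function(mask, min_object_px = 50, closing_radius = 2) {
  if (!is.matrix(mask) || !is.logical(mask)) {
    stop_ts("`mask` must be a logical matrix.", "tuberspec_type_error")
  }
  m <- mask * 1
  if (closing_radius > 0) {
    brush <- EBImage::makeBrush(2 * closing_radius + 1, shape = "disc")
    m <- EBImage::closing(m, brush)
  }
  m <- EBImage::fillHull(m)
  lab <- label_components8(m > 0)
  sizes <- tabulate(lab[lab > 0])
  sizes[sizes < min_object_px] <- 0L
  if (all(sizes == 0)) {
    stop_ts("No foreground component survives cleaning.", "tuberspec_empty_mask")
  }
  keep <- which.max(sizes) # ties -> lowest label (first in scan order)
  out <- lab == keep
  attr(out, "n_foreground") <- sum(out)
  out
}

# 8-connected labelling: EBImage::bwlabel is 4-connected, so merge labels that
# touch diagonally with a union-find pass.
label_components8 <- function(mask) {
  lab <- EBImage::bwlabel(mask * 1)
  lab <- matrix(as.integer(lab), nrow(lab), ncol(lab))
  n <- max(lab)
  if (n <= 1) return(lab)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  union <- function(a, b) {
    ra <- find(a); rb <- find(b)
    if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb)
  }
  nr <- nrow(lab); nc <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-nr, -nc]), as.vector(lab[-1, -1])),  # down-right
    cbind(as.vector(lab[-1, -nc]), as.vector(lab[-nr, -1]))   # up-right
  )
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 & pairs[, 1] != pairs[, 2], ,
                 drop = FALSE]
  if (nrow(pairs) > 0) {
    for (k in seq_len(nrow(pairs))) union(pairs[k, 1], pairs[k, 2])
  }
  roots <- vapply(seq_len(n), find, integer(1))
  relab <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0] <- relab[lab[lab > 0]]
  out
}

#' Jaccard overlap of two masks
#'
#' Intersection over union of two logical masks; the agreement measure used to
#' validate segmentation against a known truth mask.
#'
#' @param a,b Logical matrices of identical shape.
#' @return A number in `[0, 1]`.
#' @export
mask_jaccard <- function(a, b) {
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}
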