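# ROI segmentation: Otsu threshold, morphological closing, connected
# components. The upstream instrument's blob detection is proprietary to
# its acquisition software; this is a plain reimplementation sufficient
# for the synthetic imagery.

#' Segment a grayscale ROI image
#'
#' Thresholds the image with Otsu's method (subject to a configurable
#' floor), applies a morphological closing to bridge small gaps, and
#' returns the union of all above-threshold connected components as a
#' binary mask. An empty mask (blank image) is a valid result.
#'
#' @param image Numeric matrix in `[0, 1]`, one grayscale ROI.
#' @param threshold_floor Minimum admissible threshold; guards against
#'   Otsu collapsing on near-blank images.
#' @param closing_size Diameter (px) of the disc brush used for closing.
#' @return Integer matrix of the same dimension, 1 = object, 0 = background.
#' @export
segment_roi <- function(image, threshold_floor = 0.3, closing_size = 3) {
  if (!is.matrix(image) || !is.numeric(image)) {
    abort("`image` must be a 2-D numeric matrix.")
  }
  img <- pmin(pmax(image, 0), 1)
  thr <- tryCatch(
    EBImage::otsu(EBImage::Image(img), range = c(0, 1)),
    error = function(e) threshold_floor
  )
  thr <- max(thr, threshold_floor)
  mask <- (img > thr) * 1
  if (sum(mask) > 0 && closing_size > 1) {
    brush <- EBImage::makeBrush(closing_size, shape = "disc")
    mask <- EBImage::imageData(
      EBImage::closing(EBImage::Image(mask), brush)
    )
  }
  storage.mode(mask) <- "integer"
  matrix(mask, nrow = nrow(image), ncol = ncol(image))
}

#' Label connected components of a binary mask
#'
#' @param mask Binary matrix (0/1).
#' @return Integer matrix of component labels (0 = background).
#' @export
label_blobs <- function(mask) {
  .check_mask(mask)
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask)))
  storage.mode(lab) <- "integer"
  matrix(lab, nrow = nrow(mask), ncol = ncol(mask))
}

.check_mask <- function(mask) {
  if (!is.matrix(mask)) abort("`mask` must be a 2-D matrix.")
  v <- unique(as.vector(mask))
  if (!all(v %in% c(0, 1))) abort("`mask` must be binary (0/1).")
  invisible(mask)
}
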