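# Shape + texture feature extraction for ROI masks.
#
# A documented ~15-feature subset stands in for the several-hundred
# features of upstream IFCB processing chains: enough to separate the six
# synthetic morphotypes while keeping the classifier contract testable.

#' Feature vector field names
#'
#' Fixed, versioned order of the numeric image descriptors produced by
#' [extract_features()]. Classifiers trained on one version refuse
#' feature tables from another.
#'
#' @return Character vector of feature column names.
#' @export
feature_names <- function() {
  c(
    "area_um2", "perimeter_um", "equivalent_diameter_um",
    "major_axis_um", "minor_axis_um", "elongation", "solidity",
    "extent_ratio", "n_blobs", "summed_blob_area_um2",
    "intensity_mean", "intensity_var", "intensity_entropy",
    "biovolume_um3"
  )
}

#' Feature set version stamp
#' @return Single character version string.
#' @export
feature_version <- function() "underice-features-1"

.hull_area <- function(rows, cols) {
  # hull of pixel corners so a 1-px line still has positive area
  px <- cbind(
    c(cols - 0.5, cols - 0.5, cols + 0.5, cols + 0.5),
    c(rows - 0.5, rows + 0.5, rows - 0.5, rows + 0.5)
  )
  h <- grDevices::chull(px)
  hx <- px[h, 1]; hy <- px[h, 2]
  abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
}

.perimeter_px <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(0L, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- mask
  ri <- 2:(nr + 1); ci <- 2:(nc + 1)
  exposed <- (pad[ri - 1, ci] == 0) + (pad[ri + 1, ci] == 0) +
    (pad[ri, ci - 1] == 0) + (pad[ri, ci + 1] == 0)
  sum(exposed[mask == 1])
}

#' Extract image features
#'
#' Computes the fixed-order feature vector (see [feature_names()]) for
#' one ROI: mask-derived shape descriptors (area, perimeter, equivalent
#' diameter, principal-axis lengths from second moments, elongation,
#' solidity, bounding-box extent ratio, blob count and summed blob area),
#' texture summaries of the intensities under the mask (mean, variance,
#' 32-bin entropy), and the distance-map biovolume.
#'
#' An empty mask yields all-zero shape features and zero biovolume.
#'
#' @param image Numeric matrix in `[0, 1]`.
#' @param mask Binary matrix of the same dimension (see [segment_roi()]).
#' @param pixel_scale um per px.
#' @return One-row tibble with `feature_version` attribute.
#' @export
extract_features <- function(image, mask, pixel_scale = 1) {
  if (!is.matrix(image)) abort("`image` must be a 2-D numeric matrix.")
  .check_mask(mask)
  if (!all(dim(image) == dim(mask))) {
    abort("`image` and `mask` dimensions must agree.")
  }
  if (pixel_scale <= 0) abort("`pixel_scale` must be positive.")

  n_px <- sum(mask)
  if (n_px == 0) {
    out <- as_tibble(setNames(as.list(rep(0, length(feature_names()))),
                              feature_names()))
    attr(out, "feature_version") <- feature_version()
    return(out)
  }

  idx <- which(mask == 1, arr.ind = TRUE)
  rows <- idx[, 1]; cols <- idx[, 2]
  area <- n_px * pixel_scale^2
  perim <- .perimeter_px(mask) * pixel_scale
  eq_diam <- 2 * sqrt(area / pi)

  # principal axes from second central moments (ellipse convention)
  if (n_px > 1) {
    cc <- cbind(cols, rows)
    cv <- stats::cov(cc) * (n_px - 1) / n_px + diag(2) / 12
    ev <- eigen(cv, symmetric = TRUE)$values
    major <- 4 * sqrt(max(ev[1], 0)) * pixel_scale
    minor <- 4 * sqrt(max(ev[2], 1e-12)) * pixel_scale
  } else {
    major <- minor <- pixel_scale
  }
  elong <- max(major / minor, 1)

  hull <- max(.hull_area(rows, cols), n_px) * pixel_scale^2
  solidity <- min(area / hull, 1)
  bbox <- (diff(range(rows)) + 1) * (diff(range(cols)) + 1) * pixel_scale^2
  extent_ratio <- area / bbox

  lab <- label_blobs(mask)
  n_blobs <- max(lab)
  blob_area <- area # union of components equals the mask

  vals <- image[mask == 1]
  i_mean <- mean(vals)
  i_var <- if (n_px > 1) var(vals) else 0
  counts <- tabulate(pmin(floor(pmin(pmax(vals, 0), 1) * 32) + 1, 32), 32)
  p <- counts[counts > 0] / n_px
  i_ent <- -sum(p * log2(p))

  bv <- estimate_biovolume(mask, pixel_scale)

  out <- tibble(
    area_um2 = area, perimeter_um = perim,
    equivalent_diameter_um = eq_diam,
    major_axis_um = major, minor_axis_um = minor,
    elongation = elong, solidity = solidity, extent_ratio = extent_ratio,
    n_blobs = as.numeric(n_blobs), summed_blob_area_um2 = blob_area,
    intensity_mean = i_mean, intensity_var = i_var,
    intensity_entropy = i_ent, biovolume_um3 = bv
  )
  attr(out, "feature_version") <- feature_version()
  out
}

#' Remove very small images of one class from biovolume records
#'
#' Class-specific small-object filter: records of `class_label` with
#' biovolume strictly less than `threshold_um3` are dropped; every other
#' class is untouched and record order is preserved. The default removes
#' sub-61-um^3 objects classed as Urosolenia -- chloroplast fragments
#' imaged when the fragile frustule fails to trigger a full outline,
#' whose frequency jumps with flash-lamp intensity changes.
#'
#' @param records Data frame of biovolume records with at least columns
#'   `class` and `biovolume_um3`.
#' @param class_label Class to filter.
#' @param threshold_um3 Strict lower retention bound, um^3.
#' @return Filtered tibble, same columns and order.
#' @examples
#' recs <- tibble::tibble(class = "Urosolenia", biovolume_um3 = c(10, 61, 100))
#' filter_small_images(recs)
#' @export
filter_small_images <- function(records, class_label = "Urosolenia",
                                threshold_um3 = 61) {
  if (threshold_um3 <= 0) abort("`threshold_um3` must be positive.")
  records <- as_tibble(records)
  if (nrow(records) == 0) return(records)
  dplyr::filter(
    records,
    .data$class != class_label | .data$biovolume_um3 >= threshold_um3
  )
}
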