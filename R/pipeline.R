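# End-to-end glue: images -> masks -> features -> labels -> biovolume
# records.

#' Extract features for a table of images
#'
#' Segments each image and extracts the feature vector; one row per
#' image.
#'
#' @param images Tibble with `image_id` and an `image` list-column
#'   (matrices), e.g. `generate_campaign(...)$images`.
#' @param pixel_scale um per px.
#' @return Tibble: `image_id` + the [feature_names()] columns.
#' @export
extract_campaign_features <- function(images, pixel_scale = 1) {
  if (!"image" %in% names(images)) {
    abort("`images` must carry an `image` list-column.")
  }
  feats <- purrr::map_dfr(images$image, function(im) {
    extract_features(im, segment_roi(im), pixel_scale)
  })
  dplyr::bind_cols(tibble(image_id = images$image_id), feats)
}

#' Build a labelled training database of synthetic images
#'
#' Renders `n_per_class` ROIs per taxon, extracts their features and
#' labels them with the generating class -- the stand-in for a manually
#' classified image library. An optional catch-all class of irregular
#' blob particles can be added under the label `Other`.
#'
#' @param taxa Named list of [taxon_model()]s.
#' @param n_per_class Images rendered per taxon.
#' @param n_other Irregular catch-all images labelled `Other`.
#' @param pixel_scale um per px.
#' @param seed Integer seed.
#' @return Tibble: `image_id`, `class`, feature columns.
#' @export
build_training_database <- function(taxa = default_taxa(),
                                    n_per_class = 120, n_other = 0,
                                    pixel_scale = 1, seed = 1L) {
  all_taxa <- taxa
  if (n_other > 0) {
    all_taxa <- c(all_taxa, list(
      Other = taxon_model("Other", "blob", length_um = 18,
                          abundance = function(t) 0)
    ))
  }
  withr::with_seed(seed, {
    purrr::imap_dfr(all_taxa, function(tx, nm) {
      n <- if (nm == "Other") n_other else n_per_class
      purrr::map_dfr(seq_len(n), function(i) {
        roi <- generate_roi(tx, pixel_scale = pixel_scale)
        feats <- extract_features(roi$image, segment_roi(roi$image),
                                  pixel_scale)
        dplyr::bind_cols(
          tibble(image_id = sprintf("%s_%04d", nm, i), class = nm),
          feats
        )
      })
    })
  })
}

#' Classify a campaign into biovolume records
#'
#' Runs segmentation, feature extraction and classification over every
#' campaign image and returns per-image biovolume records (class label
#' or `unclassified`, estimated biovolume) ready for
#' [filter_small_images()] and [aggregate_biovolume()].
#'
#' @param campaign An `ifcb_campaign` with rendered images.
#' @param model A [train_forest()] classifier.
#' @param vote_threshold Passed to [classify()].
#' @param pixel_scale um per px.
#' @return Tibble: `image_id`, `sample_id`, `time`, `depth_m`, `class`,
#'   `vote_fraction`, `biovolume_um3`, `true_class`.
#' @export
classify_campaign <- function(campaign, model, vote_threshold = 0.5,
                              pixel_scale = 1) {
  if (!inherits(campaign, "ifcb_campaign")) {
    abort("`campaign` must be an ifcb_campaign.")
  }
  feats <- extract_campaign_features(campaign$images, pixel_scale)
  res <- classify(model, feats, vote_threshold)
  campaign$images |>
    dplyr::select("image_id", "sample_id", "time", "depth_m",
                  "true_class") |>
    dplyr::left_join(
      dplyr::select(res, "image_id", class = "label", "vote_fraction"),
      by = "image_id"
    ) |>
    dplyr::left_join(
      dplyr::select(feats, "image_id", "biovolume_um3"),
      by = "image_id"
    )
}
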