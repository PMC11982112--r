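# Full synthetic campaigns: sample manifests, per-sample image draws,
# ground truth table.

.sample_times <- function(start, end, period_min) {
  total_min <- as.numeric(difftime(end, start, units = "mins"))
  n <- floor(total_min / period_min) # last partial interval dropped
  if (n < 1) return(as.POSIXct(character(0), tz = "UTC"))
  start + (seq_len(n) - 1) * period_min * 60
}

.season_frac <- function(time, start, end) {
  as.numeric(difftime(time, start, units = "secs")) /
    as.numeric(difftime(end, start, units = "secs"))
}

#' Expected image count multiplier with depth
#'
#' Phytoplankton concentrations decline from the well-lit near-surface
#' water towards depth; abundance trajectories are referenced to 2 m and
#' attenuated exponentially below it.
#'
#' @param depth_m Depth in metres.
#' @param scale_m e-folding depth of the attenuation, m.
#' @return Multiplier in `(0, 1]`.
#' @export
depth_attenuation <- function(depth_m, scale_m = 8) {
  exp(-pmax(depth_m - 2, 0) / scale_m)
}

#' Generate a synthetic campaign
#'
#' Draws the full sample manifest implied by a [campaign_config()], then
#' for every sample draws a Poisson number of particles per taxon
#' (expected counts follow each taxon's abundance trajectory times the
#' depth attenuation) and renders their ROI images. After the optional
#' flash-step time, the frustule-loss probability of chloroplast-imaging
#' taxa is multiplied by the configured factor, reproducing a sudden
#' excess of small fragment images. Everything is deterministic given
#' `campaign$rng_seed`.
#'
#' @param campaign A [campaign_config()].
#' @param taxa Named list of [taxon_model()]s (see [default_taxa()]).
#' @param render Logical; render image matrices (list-column `image`)?
#'   With `render = FALSE` only ground truth (class, analytic biovolume)
#'   is produced, which is enough for count-level tests and much faster.
#' @param pixel_scale um per px for rendered images.
#' @param attenuation_scale_m Passed to [depth_attenuation()].
#' @return List of class `ifcb_campaign` with elements `manifest` (tibble:
#'   `sample_id`, `time`, `depth_m`, `volume_ml`) and `images` (tibble:
#'   `image_id`, `sample_id`, `time`, `depth_m`, `true_class`,
#'   `true_biovolume_um3`, `fragment`, and if rendered an `image`
#'   list-column), plus the `campaign` and `taxa` used.
#' @export
generate_campaign <- function(campaign, taxa = default_taxa(),
                              render = TRUE, pixel_scale = 1,
                              attenuation_scale_m = 8) {
  if (!inherits(campaign, "campaign_config")) {
    abort("`campaign` must be a campaign_config.")
  }
  if (length(taxa) == 0) abort("`taxa` must be a non-empty list.")
  stopifnot(all(vapply(taxa, inherits, logical(1), "taxon_model")))

  manifest <- purrr::map2_dfr(
    campaign$depths_m, campaign$period_min,
    function(d, p) {
      tibble(
        time = .sample_times(campaign$start, campaign$end, p),
        depth_m = d
      )
    }
  )
  if (anyDuplicated(manifest[c("time", "depth_m")]) > 0) {
    abort("Overlapping sample timestamps at one depth.")
  }
  manifest <- manifest |>
    dplyr::arrange(.data$time, .data$depth_m) |>
    dplyr::mutate(
      sample_id = sprintf("D%04.1f_%s", .data$depth_m,
                          format(.data$time, "%Y%m%dT%H%M%S")),
      volume_ml = campaign$syringe_volume_ml
    ) |>
    dplyr::select("sample_id", "time", "depth_m", "volume_ml")

  images <- withr::with_seed(campaign$rng_seed, {
    purrr::pmap_dfr(manifest, function(sample_id, time, depth_m, volume_ml) {
      frac <- .season_frac(time, campaign$start, campaign$end)
      atten <- depth_attenuation(depth_m, attenuation_scale_m)
      after_flash <- !is.null(campaign$flash_step_time) &&
        time >= campaign$flash_step_time
      purrr::map_dfr(taxa, function(tx) {
        lambda <- tx$abundance(frac) * atten
        # The flash-lamp step multiplies the rate of chloroplast-fragment
        # captures; full-frustule captures are unaffected.
        frag_mult <- if (after_flash) campaign$flash_step_factor else 1
        n_full <- rpois(1, lambda * (1 - tx$frustule_loss_prob))
        n_frag <- rpois(1, lambda * tx$frustule_loss_prob * frag_mult)
        n <- n_full + n_frag
        if (n == 0) return(tibble())
        rois <- purrr::map(seq_len(n), function(i) {
          generate_roi(tx, pixel_scale = pixel_scale,
                       frustule_loss = as.numeric(i > n_full))
        })
        out <- tibble(
          sample_id = sample_id, time = time, depth_m = depth_m,
          true_class = tx$name,
          true_biovolume_um3 = vapply(rois, `[[`, numeric(1),
                                      "true_biovolume_um3"),
          fragment = vapply(rois, `[[`, logical(1), "fragment")
        )
        if (render) out$image <- purrr::map(rois, "image")
        out
      })
    })
  })
  if (nrow(images) > 0) {
    images <- images |>
      dplyr::group_by(.data$sample_id) |>
      dplyr::mutate(
        image_id = paste0(.data$sample_id, "_",
                          sprintf("%05d", dplyr::row_number()))
      ) |>
      dplyr::ungroup() |>
      dplyr::relocate("image_id")
  }
  structure(
    list(manifest = manifest, images = images,
         campaign = campaign, taxa = taxa),
    class = "ifcb_campaign"
  )
}

#' @export
print.ifcb_campaign <- function(x, ...) {
  cat("<ifcb_campaign>", nrow(x$manifest), "samples,",
      nrow(x$images), "images,",
      length(unique(x$manifest$depth_m)), "depths\n")
  invisible(x)
}

#' Write a campaign to disk as plain files
#'
#' Emits 8-bit grayscale PNGs plus a manifest CSV (`sample_id`,
#' `iso8601_time`, `depth_m`, `volume_ml`, `image_path`) and a ground
#' truth CSV (`sample_id`, `image_path`, `true_class`,
#' `true_biovolume_um3`).
#'
#' @param campaign An `ifcb_campaign` with rendered images.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_campaign <- function(campaign, dir) {
  rlang::check_installed("png")
  if (!inherits(campaign, "ifcb_campaign")) {
    abort("`campaign` must be an ifcb_campaign.")
  }
  if (!"image" %in% names(campaign$images)) {
    abort("Campaign has no rendered images (use render = TRUE).")
  }
  dir.create(file.path(dir, "images"), recursive = TRUE,
             showWarnings = FALSE)
  imgs <- campaign$images
  paths <- file.path("images", paste0(imgs$image_id, ".png"))
  purrr::walk2(imgs$image, paths, function(im, p) {
    png::writePNG(im, file.path(dir, p))
  })
  manifest <- campaign$manifest |>
    dplyr::mutate(iso8601_time = format(.data$time, "%Y-%m-%dT%H:%M:%SZ")) |>
    dplyr::left_join(
      tibble(sample_id = imgs$sample_id, image_path = paths),
      by = "sample_id"
    ) |>
    dplyr::select("sample_id", "iso8601_time", "depth_m", "volume_ml",
                  "image_path")
  readr::write_csv(manifest, file.path(dir, "manifest.csv"))
  truth <- tibble(
    sample_id = imgs$sample_id, image_path = paths,
    true_class = imgs$true_class,
    true_biovolume_um3 = imgs$true_biovolume_um3
  )
  readr::write_csv(truth, file.path(dir, "ground_truth.csv"))
  invisible(dir)
}
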