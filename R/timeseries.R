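# Per-sample, per-class biovolume aggregation and smoothing.

#' Aggregate biovolume records to per-mL concentrations
#'
#' Per sample and class: sum of image biovolumes divided by the analysed
#' volume. Classes present in `classes` but absent from a sample are
#' reported as explicit zeros, so every sample carries a complete class
#' vector (including 'Other' and 'unclassified' series, which are never
#' silently dropped).
#'
#' @param records Tibble of per-image biovolume records: `sample_id`,
#'   `class`, `biovolume_um3`.
#' @param manifest Sample manifest: `sample_id`, `time`, `depth_m`,
#'   `volume_ml` (> 0).
#' @param classes Classes to report; default: all classes present in
#'   `records`.
#' @return Tibble with `sample_id`, `time`, `depth_m`, `class`,
#'   `biovolume_um3_per_ml`, one row per (sample, class).
#' @export
aggregate_biovolume <- function(records, manifest, classes = NULL) {
  records <- as_tibble(records)
  manifest <- as_tibble(manifest)
  if (any(manifest$volume_ml <= 0)) {
    abort("`volume_ml` must be positive for every sample.")
  }
  classes <- classes %||% sort(unique(records$class))
  sums <- records |>
    dplyr::group_by(.data$sample_id, .data$class) |>
    dplyr::summarise(total_um3 = sum(.data$biovolume_um3), .groups = "drop")
  manifest |>
    dplyr::select("sample_id", "time", "depth_m", "volume_ml") |>
    tidyr::expand_grid(class = classes) |>
    dplyr::left_join(sums, by = c("sample_id", "class")) |>
    dplyr::mutate(
      biovolume_um3_per_ml =
        dplyr::coalesce(.data$total_um3, 0) / .data$volume_ml
    ) |>
    dplyr::select("sample_id", "time", "depth_m", "class",
                  "biovolume_um3_per_ml")
}

#' Centred moving average of a biovolume series
#'
#' For each sample, the mean over all samples of the same depth and
#' class within +/- `window_h` hours. Windows containing no samples
#' cannot occur (each window contains at least its own sample).
#'
#' @param series Tibble from [aggregate_biovolume()].
#' @param window_h Half-window in hours.
#' @return `series` with an added `smoothed_um3_per_ml` column.
#' @export
biovolume_moving_average <- function(series, window_h = 12) {
  series <- dplyr::arrange(as_tibble(series), .data$time)
  series |>
    dplyr::group_by(.data$depth_m, .data$class) |>
    dplyr::group_modify(function(d, key) {
      t_num <- as.numeric(d$time)
      lo <- findInterval(t_num - window_h * 3600 - 1e-6, t_num) + 1
      hi <- findInterval(t_num + window_h * 3600 + 1e-6, t_num)
      cum <- c(0, cumsum(d$biovolume_um3_per_ml))
      tot <- cum[hi + 1] - cum[lo]
      d$smoothed_um3_per_ml <- tot / (hi - lo + 1)
      d
    }) |>
    dplyr::ungroup()
}

#' Per-depth sample frequency report
#'
#' Counts samples per depth and the ratio of the shallow-depth to the
#' deepest-depth sampling frequency (per-depth mean count at the
#' non-deepest depths over the deepest depth's count).
#'
#' @param manifest Sample manifest (`sample_id`, `depth_m`).
#' @return List with `counts` (tibble `depth_m`, `n`) and
#'   `shallow_to_deep_ratio` (NA, with a message, for a single depth or
#'   empty manifest).
#' @export
depth_frequency_report <- function(manifest) {
  manifest <- as_tibble(manifest)
  counts <- dplyr::count(manifest, .data$depth_m)
  ratio <- if (nrow(counts) < 2) {
    NA_real_
  } else {
    deep <- counts$n[which.max(counts$depth_m)]
    mean(counts$n[-which.max(counts$depth_m)]) / deep
  }
  list(counts = counts, shallow_to_deep_ratio = ratio)
}

#' Export biovolume records in the archive column layout
#'
#' Writes one row per image: sampling time (ISO 8601), depth (m),
#' sample volume (mL), phytoplankton class, estimated biovolume (um^3).
#'
#' @param records Per-image records joined with sample metadata
#'   (`time`, `depth_m`, `volume_ml`, `class`, `biovolume_um3`).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_biovolume_records <- function(records, path) {
  out <- tibble(
    sampling_time = format(records$time, "%Y-%m-%dT%H:%M:%SZ"),
    depth_m = records$depth_m,
    sample_volume_ml = records$volume_ml,
    phytoplankton_class = records$class,
    estimated_biovolume_um3 = records$biovolume_um3
  )
  readr::write_csv(out, path)
  invisible(path)
}
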