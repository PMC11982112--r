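# Verification samples: the manual-classification benchmark schedule and
# the auto-vs-manual comparison.

#' Draw a verification-sample schedule
#'
#' Splits the campaign into consecutive two-week windows from the first
#' sample time and draws, without replacement and reproducibly by seed,
#' up to `per_period` sample ids per window (all of them when a window
#' holds fewer).
#'
#' @param manifest Sample manifest tibble (`sample_id`, `time`).
#' @param per_period Samples drawn per window.
#' @param period_days Window length in days.
#' @param seed Integer seed.
#' @return Character vector of selected `sample_id`s, in time order.
#' @export
verification_schedule <- function(manifest, per_period = 3,
                                  period_days = 14, seed = 1L) {
  manifest <- as_tibble(manifest)
  if (nrow(manifest) == 0) return(character(0))
  t0 <- min(manifest$time)
  win <- floor(as.numeric(difftime(manifest$time, t0, units = "days")) /
                 period_days)
  picks <- withr::with_seed(seed, {
    manifest |>
      dplyr::mutate(window = win) |>
      dplyr::group_by(.data$window) |>
      dplyr::slice_sample(n = per_period) |>
      dplyr::ungroup()
  })
  picks |>
    dplyr::arrange(.data$time) |>
    dplyr::pull(.data$sample_id)
}

#' Compare automatic and manual classifications
#'
#' Builds the per-class contingency between an auto-classification
#' result and manual labels over the same image set: a confusion
#' matrix, per-class counts for both assessors, and agreement rates.
#' In synthetic campaigns the "manual" labels are the generator's
#' ground truth.
#'
#' @param auto Tibble with `image_id`, `label` (see [classify()]).
#' @param manual Tibble with `image_id`, `label`.
#' @return A `verification_comparison`: list with `confusion` (table,
#'   manual rows x auto columns), `counts` (tibble `class`, `n_auto`,
#'   `n_manual`), `agreement` (fraction of identically labelled images)
#'   and `agreement_accepted` (same, over auto-accepted images only).
#' @export
verification_compare <- function(auto, manual) {
  auto <- as_tibble(auto)
  manual <- as_tibble(manual)
  if (!setequal(auto$image_id, manual$image_id) ||
      nrow(auto) != nrow(manual)) {
    abort("`auto` and `manual` must cover the same image set.")
  }
  joined <- dplyr::inner_join(
    dplyr::select(auto, "image_id", auto_label = "label"),
    dplyr::select(manual, "image_id", manual_label = "label"),
    by = "image_id"
  )
  levels_all <- sort(unique(c(joined$auto_label, joined$manual_label)))
  confusion <- table(
    manual = factor(joined$manual_label, levels = levels_all),
    auto = factor(joined$auto_label, levels = levels_all)
  )
  counts <- tibble(
    class = levels_all,
    n_auto = as.integer(table(factor(joined$auto_label, levels_all))),
    n_manual = as.integer(table(factor(joined$manual_label, levels_all)))
  )
  accepted <- joined$auto_label != "unclassified"
  structure(
    list(
      confusion = confusion, counts = counts,
      agreement = mean(joined$auto_label == joined$manual_label),
      agreement_accepted = if (any(accepted)) {
        mean(joined$auto_label[accepted] == joined$manual_label[accepted])
      } else {
        NaN
      }
    ),
    class = "verification_comparison"
  )
}

#' @export
print.verification_comparison <- function(x, ...) {
  cat("<verification_comparison>",
      sprintf("agreement %.1f%% (accepted: %.1f%%)\n",
              100 * x$agreement, 100 * x$agreement_accepted))
  print(x$counts)
  invisible(x)
}

#' Tidy a verification comparison
#'
#' @param x A `verification_comparison`.
#' @param ... Unused.
#' @return Long tibble of the confusion matrix (`manual`, `auto`, `n`).
#' @export
tidy.verification_comparison <- function(x, ...) {
  as_tibble(as.data.frame(x$confusion, stringsAsFactors = FALSE)) |>
    dplyr::rename(n = "Freq") |>
    dplyr::mutate(n = as.integer(.data$n))
}
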