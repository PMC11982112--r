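# ggplot2 displays for sections, biovolume series and grid results.

#' Plot a time-depth section
#'
#' Raster plot with depth increasing downwards; masked cells are left
#' blank. Colour limits can be clamped for display (values outside the
#' range are squished to its ends, mimicking range-restricted section
#' plots).
#'
#' @param object An `ice_section`.
#' @param limits Optional length-2 colour-scale limits.
#' @param trans Scale transform (e.g. `"log10"`).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ice_section <- function(object, limits = NULL,
                                 trans = "identity", ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$depth_m,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse(name = "Depth (m)") +
    ggplot2::scale_fill_viridis_c(
      name = paste0(object$variable,
                    if (nzchar(object$units)) paste0(" (", object$units, ")")),
      limits = limits, trans = trans, oob = scales_squish, na.value = "black"
    ) +
    ggplot2::labs(x = NULL) +
    ggplot2::theme_minimal()
}

# minimal squish so we need not depend on scales directly
scales_squish <- function(x, range = c(0, 1), ...) {
  pmin(pmax(x, range[1]), range[2])
}

#' Plot per-taxon biovolume time series
#'
#' One panel per class, points per sample coloured by depth, with the
#' smoothed series overlaid when present.
#'
#' @param series Tibble from [aggregate_biovolume()] (optionally after
#'   [biovolume_moving_average()]).
#' @param classes Classes to show (default all).
#' @return A ggplot.
#' @export
plot_biovolume_series <- function(series, classes = NULL) {
  if (!is.null(classes)) {
    series <- dplyr::filter(series, .data$class %in% classes)
  }
  p <- ggplot2::ggplot(series, ggplot2::aes(
    .data$time, .data$biovolume_um3_per_ml,
    colour = factor(.data$depth_m)
  )) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::facet_wrap(~class, scales = "free_y") +
    ggplot2::labs(
      x = NULL, y = expression(Biovolume ~ (mu * m^3 ~ mL^-1)),
      colour = "Depth (m)"
    ) +
    ggplot2::theme_minimal()
  if ("smoothed_um3_per_ml" %in% names(series)) {
    p <- p + ggplot2::geom_line(
      ggplot2::aes(y = .data$smoothed_um3_per_ml), linewidth = 0.5
    )
  }
  p
}

#' Plot classifier grid results
#'
#' Error rate against training-set range for each tree count.
#'
#' @param object A `classifier_grid` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.classifier_grid <- function(object, ...) {
  ok <- dplyr::filter(as_tibble(object), .data$status == "ok")
  ggplot2::ggplot(ok, ggplot2::aes(
    interaction(.data$min_n, .data$max_n, sep = "-"),
    .data$error_rate, colour = factor(.data$n_trees),
    group = factor(.data$n_trees)
  )) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::labs(x = "min-max training images per category",
                  y = "Accepted-classification error rate",
                  colour = "Trees") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60,
                                                       hjust = 1))
}

#' Tidy a classifier grid
#'
#' @param x A `classifier_grid`.
#' @param ... Unused.
#' @return The grid metrics without the model list-column.
#' @export
tidy.classifier_grid <- function(x, ...) {
  dplyr::select(as_tibble(x), -"model")
}

#' Summarise a classifier grid
#'
#' @param x A `classifier_grid`.
#' @param ... Unused.
#' @return One-row tibble describing the selected best candidate and
#'   grid bookkeeping.
#' @export
glance.classifier_grid <- function(x, ...) {
  best <- select_best(x)
  tibble(
    n_candidates = nrow(x),
    n_failed = sum(x$status != "ok"),
    best_min_n = best$min_n, best_max_n = best$max_n,
    best_n_trees = best$n_trees,
    best_error_rate = best$error_rate,
    best_unclassified_fraction = best$unclassified_fraction
  )
}

#' Tidy a fitted plankton classifier
#'
#' @param x A `plankton_classifier`.
#' @param ... Unused.
#' @return Tibble of per-feature importance (mean Gini decrease).
#' @export
tidy.plankton_classifier <- function(x, ...) {
  imp <- randomForest::importance(x$forest)
  tibble(
    feature = rownames(imp),
    importance = as.numeric(imp[, 1])
  ) |>
    dplyr::arrange(dplyr::desc(.data$importance))
}

#' Summarise a fitted plankton classifier
#'
#' @param x A `plankton_classifier`.
#' @param ... Unused.
#' @return One-row tibble: categories, trees, out-of-bag error.
#' @export
glance.plankton_classifier <- function(x, ...) {
  tibble(
    n_categories = length(x$categories),
    n_trees = x$n_trees,
    oob_error = tail(x$forest$err.rate[, "OOB"], 1)
  )
}
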