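# Balanced random-forest classifier selection.
#
# The classifier itself is bagged decision trees (the randomForest
# package); what is implemented here is the selection protocol around
# it: per-category training-set balancing between a minimum and maximum
# image count, exclusion of under-represented categories and of the
# catch-all 'Other' class, a vote-fraction threshold that routes
# low-confidence images to 'unclassified', and a deterministic search
# over a grid of (min_n, max_n, n_trees) candidates scored by
# accepted-classification error rate.

#' Enumerate the classifier candidate grid
#'
#' Full Cartesian product of minimum counts, maximum counts and tree
#' counts, in deterministic order. No `max >= min` constraint is
#' applied at enumeration time: the canonical 4 minima x 7 maxima grid
#' counts 28 ranges (56 candidates with two tree counts) only if
#' degenerate pairs are kept; they are recorded as failed candidates
#' when trained.
#'
#' @param min_values Candidate minimum images per category.
#' @param max_values Candidate maximum images per category.
#' @param tree_counts Candidate numbers of trees.
#' @return Tibble with columns `min_n`, `max_n`, `n_trees`.
#' @examples
#' nrow(enumerate_grid()) # 56
#' @export
enumerate_grid <- function(min_values = seq(200, 500, by = 100),
                           max_values = seq(300, 900, by = 100),
                           tree_counts = c(25, 50)) {
  if (length(min_values) == 0 || length(max_values) == 0 ||
      length(tree_counts) == 0) {
    abort("Grid value lists must be non-empty.")
  }
  tidyr::expand_grid(
    min_n = min_values, max_n = max_values, n_trees = tree_counts
  )
}

#' Assemble a balanced training set
#'
#' From a labelled feature database, keeps categories with at least
#' `min_n` images (others are excluded and reported), subsamples
#' categories above `max_n` down to `max_n` reproducibly by seed, and
#' always drops the catch-all 'Other' category, which is never trained
#' on.
#'
#' @param database Tibble with one row per image: an `image_id` column,
#'   a `class` column, and the [feature_names()] columns.
#' @param min_n,max_n Per-category image count bounds; `min_n <= max_n`
#'   is required here (grid pairs violating it are handled upstream as
#'   failed candidates).
#' @param seed Integer seed for the subsampling.
#' @param other_label Catch-all label excluded from training.
#' @return List of class `training_set`: `data` (tibble), `categories`,
#'   `excluded` (tibble `class`, `n`, `reason`), `min_n`, `max_n`,
#'   `seed`.
#' @export
assemble_training_set <- function(database, min_n, max_n, seed = 1L,
                                  other_label = "Other") {
  database <- as_tibble(database)
  if (nrow(database) == 0) abort("`database` is empty.")
  if (min_n > max_n) {
    abort("`min_n` must be <= `max_n` (degenerate candidate).")
  }
  if (anyDuplicated(database$image_id) > 0) {
    abort("`database` contains duplicate image ids.")
  }
  database <- dplyr::filter(database, .data$class != other_label)
  counts <- dplyr::count(database, .data$class)
  excluded <- counts |>
    dplyr::filter(.data$n < min_n) |>
    dplyr::mutate(reason = "below minimum image count")
  kept <- setdiff(counts$class, excluded$class)
  data <- withr::with_seed(seed, {
    database |>
      dplyr::filter(.data$class %in% kept) |>
      dplyr::group_by(.data$class) |>
      dplyr::slice_sample(n = max_n) |>
      dplyr::ungroup()
  })
  structure(
    list(
      data = data, categories = sort(kept), excluded = excluded,
      min_n = min_n, max_n = max_n, seed = seed
    ),
    class = "training_set"
  )
}

#' @export
print.training_set <- function(x, ...) {
  cat("<training_set>", length(x$categories), "categories,",
      nrow(x$data), "images (min", x$min_n, "max", x$max_n, ")\n")
  if (nrow(x$excluded) > 0) {
    cat("  excluded:", paste(x$excluded$class, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Train a bagged-tree classifier
#'
#' Random forest over the fixed-order feature columns; deterministic
#' given `seed`.
#'
#' @param training_set A [assemble_training_set()] result (or a plain
#'   tibble with `class` + feature columns).
#' @param n_trees Number of trees.
#' @param seed Integer seed.
#' @return A `plankton_classifier`: the fitted forest plus the feature
#'   column order, category levels and a feature-version stamp.
#' @export
train_forest <- function(training_set, n_trees = 50, seed = 1L) {
  data <- if (inherits(training_set, "training_set")) {
    training_set$data
  } else {
    as_tibble(training_set)
  }
  feats <- intersect(feature_names(), names(data))
  if (length(feats) < 2) abort("Training data lacks feature columns.")
  classes <- sort(unique(data$class))
  if (length(classes) < 2) {
    abort("Training requires at least 2 categories.")
  }
  y <- factor(data$class, levels = classes)
  x <- as.data.frame(data[feats])
  fit <- withr::with_seed(seed, {
    randomForest::randomForest(x = x, y = y, ntree = n_trees)
  })
  structure(
    list(
      forest = fit, features = feats, categories = classes,
      n_trees = n_trees, seed = seed,
      feature_version = feature_version()
    ),
    class = "plankton_classifier"
  )
}

#' @export
print.plankton_classifier <- function(x, ...) {
  cat("<plankton_classifier>", length(x$categories), "categories,",
      x$n_trees, "trees\n")
  invisible(x)
}

#' Classify feature vectors
#'
#' Each image is assigned the category chosen by the most trees; if the
#' winning vote fraction falls below `vote_threshold` the image is
#' labelled `unclassified`. Vote ties break to the lexicographically
#' first category name.
#'
#' @param model A [train_forest()] classifier.
#' @param features Tibble with the model's feature columns (and
#'   optionally `image_id`).
#' @param vote_threshold Minimum winning vote fraction for an accepted
#'   classification, in `[0, 1]`.
#' @return Tibble with `image_id` (generated if absent), `label`
#'   (category or `"unclassified"`) and `vote_fraction`.
#' @export
classify <- function(model, features, vote_threshold = 0.5) {
  if (!inherits(model, "plankton_classifier")) {
    abort("`model` must be a plankton_classifier.")
  }
  features <- as_tibble(features)
  missing_cols <- setdiff(model$features, names(features))
  if (length(missing_cols) > 0) {
    abort(paste0("Feature dimension mismatch; missing: ",
                 paste(missing_cols, collapse = ", ")))
  }
  ids <- features$image_id %||% sprintf("img_%05d", seq_len(nrow(features)))
  votes <- predict(model$forest,
                   newdata = as.data.frame(features[model$features]),
                   type = "vote", norm.votes = TRUE)
  votes <- votes[, sort(colnames(votes)), drop = FALSE]
  win <- max.col(votes, ties.method = "first") # first = lexicographic
  frac <- votes[cbind(seq_len(nrow(votes)), win)]
  label <- colnames(votes)[win]
  label[frac < vote_threshold] <- "unclassified"
  tibble(image_id = ids, label = label, vote_fraction = frac)
}

#' Evaluate a classifier on held-out data
#'
#' Two metrics, matching how selection winners are reported: the error
#' rate among accepted (non-unclassified) images, and the fraction of
#' all images left unclassified. A model that rejects everything has an
#' undefined error rate, reported as NaN with `degenerate = TRUE`.
#'
#' @param model A [train_forest()] classifier.
#' @param heldout Tibble with `class` plus feature columns, disjoint
#'   from the training images.
#' @param vote_threshold Passed to [classify()].
#' @return One-row tibble: `error_rate`, `unclassified_fraction`,
#'   `n_heldout`, `degenerate`.
#' @export
evaluate_candidate <- function(model, heldout, vote_threshold = 0.5) {
  heldout <- as_tibble(heldout)
  if (nrow(heldout) == 0) abort("`heldout` is empty.")
  res <- classify(model, heldout, vote_threshold)
  accepted <- res$label != "unclassified"
  unc_frac <- mean(!accepted)
  err <- if (any(accepted)) {
    mean(res$label[accepted] != heldout$class[accepted])
  } else {
    NaN
  }
  tibble(
    error_rate = err, unclassified_fraction = unc_frac,
    n_heldout = nrow(heldout), degenerate = !any(accepted)
  )
}

#' Run the classifier selection grid
#'
#' Stratified 80/20 train/hold-out split of the database (fixed by
#' `seed`), then for every `(min_n, max_n, n_trees)` candidate:
#' assemble a balanced training set from the training pool, train, and
#' evaluate on the held-out pool. Degenerate pairs (`max_n < min_n`) and
#' assemblies with fewer than two eligible categories are recorded as
#' failed candidates rather than errors.
#'
#' @param database Labelled feature tibble (`image_id`, `class`,
#'   feature columns).
#' @param grid Candidate tibble from [enumerate_grid()].
#' @param vote_threshold Vote-fraction threshold for acceptance.
#' @param seed Integer seed governing the split, subsampling and forest.
#' @param holdout_fraction Held-out fraction of each class.
#' @return A `classifier_grid` tibble: the grid columns plus `status`
#'   (`"ok"`/`"failed"`), `error_rate`, `unclassified_fraction`,
#'   `n_train`, `n_excluded`, and a `model` list-column.
#' @export
run_classifier_grid <- function(database, grid = enumerate_grid(),
                                vote_threshold = 0.5, seed = 1L,
                                holdout_fraction = 0.2) {
  database <- as_tibble(database)
  split <- withr::with_seed(seed, {
    database |>
      dplyr::group_by(.data$class) |>
      dplyr::mutate(
        heldout = dplyr::row_number() %in%
          sample(dplyr::n(), round(dplyr::n() * holdout_fraction))
      ) |>
      dplyr::ungroup()
  })
  train_pool <- dplyr::filter(split, !.data$heldout)
  heldout <- dplyr::filter(split, .data$heldout)

  res <- purrr::pmap_dfr(grid, function(min_n, max_n, n_trees) {
    row <- tibble(
      min_n = min_n, max_n = max_n, n_trees = n_trees,
      status = "failed", error_rate = NA_real_,
      unclassified_fraction = NA_real_, n_train = NA_integer_,
      n_excluded = NA_integer_, model = list(NULL)
    )
    ts <- tryCatch(
      assemble_training_set(train_pool, min_n, max_n, seed = seed),
      error = function(e) NULL
    )
    if (is.null(ts) || length(ts$categories) < 2) return(row)
    model <- train_forest(ts, n_trees = n_trees, seed = seed)
    ev <- evaluate_candidate(
      model, dplyr::filter(heldout, .data$class %in% ts$categories),
      vote_threshold
    )
    row$status <- "ok"
    row$error_rate <- ev$error_rate
    row$unclassified_fraction <- ev$unclassified_fraction
    row$n_train <- nrow(ts$data)
    row$n_excluded <- nrow(ts$excluded)
    row$model <- list(model)
    row
  })
  class(res) <- c("classifier_grid", class(res))
  res
}

#' Select the best classifier candidate
#'
#' Deterministic ranking of successful candidates: minimum accepted-
#' classification error rate; ties broken by lower unclassified
#' fraction, then fewer training images, then fewer trees.
#'
#' @param candidates A `classifier_grid` tibble (or any tibble with the
#'   same metric columns).
#' @return The single best candidate row (tibble).
#' @export
select_best <- function(candidates) {
  ok <- dplyr::filter(as_tibble(candidates), .data$status == "ok",
                      !is.na(.data$error_rate))
  if (nrow(ok) == 0) abort("No successfully trained candidates.")
  ok |>
    dplyr::arrange(.data$error_rate, .data$unclassified_fraction,
                   .data$n_train, .data$n_trees) |>
    dplyr::slice(1)
}
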