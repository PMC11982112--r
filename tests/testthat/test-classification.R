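# Grid enumeration, training-set balancing, forest training, the
# unclassified contract, candidate selection, verification.

test_that("grid enumeration is the full Cartesian product", {
  grid <- enumerate_grid()
  expect_equal(nrow(dplyr::distinct(grid, min_n, max_n)), 28)
  expect_equal(nrow(grid), 56)
  expect_equal(nrow(enumerate_grid(200, 300, 25)), 1)
  expect_error(enumerate_grid(numeric(0), 300, 25), "non-empty")

  withr::with_seed(8, {
    for (i in 1:5) {
      mins <- sample(100:500, sample(2:5, 1))
      maxs <- sample(300:900, sample(2:6, 1))
      trees <- sample(c(10, 25, 50), sample(1:2, 1))
      expect_equal(nrow(enumerate_grid(mins, maxs, trees)),
                   length(mins) * length(maxs) * length(trees))
    }
  })
})

test_that("training sets are balanced, reproducible, and exclude 'Other'", {
  db <- dplyr::bind_rows(
    gaussian_features(450, "under", seed = 1),
    gaussian_features(1200, "over", seed = 2),
    gaussian_features(600, "mid", seed = 3),
    gaussian_features(300, "Other", seed = 4)
  )
  ts <- assemble_training_set(db, min_n = 500, max_n = 700, seed = 9)
  expect_equal(ts$excluded$class, "under")
  expect_false("Other" %in% ts$categories)
  counts <- table(ts$data$class)
  expect_equal(as.integer(counts[["over"]]), 700)
  expect_equal(as.integer(counts[["mid"]]), 600)

  ts2 <- assemble_training_set(db, min_n = 500, max_n = 700, seed = 9)
  expect_identical(dplyr::arrange(ts$data, image_id),
                   dplyr::arrange(ts2$data, image_id))

  ok <- assemble_training_set(db, min_n = 200, max_n = 2000, seed = 1)
  expect_equal(nrow(ok$excluded), 0)

  expect_error(assemble_training_set(db, 700, 500), "degenerate")
  expect_error(assemble_training_set(db[0, ], 1, 2), "empty")
})

test_that("forests separate separable classes and not inseparable ones", {
  sep <- gaussian_features(120, c("A", "B"), sep = 5, seed = 2)
  train <- dplyr::filter(sep, as.integer(sub(".*_", "", image_id)) <= 90)
  held <- dplyr::filter(sep, as.integer(sub(".*_", "", image_id)) > 90)
  model <- train_forest(train, n_trees = 25, seed = 4)
  ev <- evaluate_candidate(model, held, vote_threshold = 0)
  expect_lte(ev$error_rate, 0.05)

  # identical feature distributions: chance-level error
  same <- gaussian_features(250, c("A", "B"), sep = 0, seed = 6)
  m2 <- train_forest(same, n_trees = 25, seed = 4)
  probe <- gaussian_features(150, c("A", "B"), sep = 0, seed = 7)
  ev2 <- evaluate_candidate(m2, probe, vote_threshold = 0)
  expect_gt(ev2$error_rate, 0.4)
  expect_lt(ev2$error_rate, 0.6)

  # determinism: same seed, same predictions
  m3 <- train_forest(train, n_trees = 25, seed = 4)
  expect_identical(classify(m3, held), classify(model, held))

  expect_error(train_forest(dplyr::filter(sep, class == "A"), 25, 1),
               "2 categories")
})

test_that("the vote threshold routes low-confidence images aside", {
  sep <- gaussian_features(100, c("A", "B"), sep = 6, seed = 3)
  model <- train_forest(sep, n_trees = 25, seed = 1)

  far <- sep[1, ] # deep inside class A
  res <- classify(model, far, vote_threshold = 0.5)
  expect_equal(res$label, "A")
  expect_equal(res$vote_fraction, 1.0)

  # threshold 0: never unclassified; threshold 1 on a midpoint: rejected
  midpoint <- tibble::tibble(
    image_id = "mid", area_um2 = mean(sep$area_um2),
    perimeter_um = mean(sep$perimeter_um), elongation = 2
  )
  r0 <- classify(model, midpoint, vote_threshold = 0)
  expect_false(r0$label == "unclassified")
  r1 <- classify(model, midpoint, vote_threshold = 1)
  expect_equal(r1$label, "unclassified")

  expect_error(classify(model, midpoint[, -2]), "mismatch")
})

test_that("degenerate evaluations are flagged, not crashed", {
  sep <- gaussian_features(80, c("A", "B"), sep = 0.5, seed = 5)
  model <- train_forest(sep, n_trees = 25, seed = 1)
  probe <- gaussian_features(40, c("A", "B"), sep = 0.5, seed = 8)
  ev <- evaluate_candidate(model, probe, vote_threshold = 1)
  if (ev$degenerate) {
    expect_true(is.nan(ev$error_rate))
    expect_equal(ev$unclassified_fraction, 1)
  } else {
    expect_gte(ev$unclassified_fraction, 0.5)
  }
  expect_error(evaluate_candidate(model, probe[0, ]), "empty")
})

test_that("candidate selection minimises error with stated tie-breaks", {
  cands <- tibble::tibble(
    min_n = c(200, 200, 300, 300), max_n = c(300, 400, 500, 600),
    n_trees = c(25, 50, 25, 50), status = c("ok", "ok", "ok", "failed"),
    error_rate = c(0.10, 0.13, 0.10, NA),
    unclassified_fraction = c(0.3, 0.2, 0.2, NA),
    n_train = c(500, 600, 400, NA)
  )
  best <- select_best(cands)
  # min error 0.10 tie -> lower unclassified wins
  expect_equal(best$max_n, 500)
  expect_equal(select_best(cands[2, ])$max_n, 400)
  expect_error(select_best(dplyr::filter(cands, status == "failed")),
               "No successfully")
})

test_that("grid search records degenerate pairs as failed candidates", {
  db <- dplyr::bind_rows(
    gaussian_features(120, c("A", "B", "C"), sep = 5, seed = 2)
  )
  grid <- enumerate_grid(c(40, 200), c(30, 90), 15)
  res <- run_classifier_grid(db, grid, seed = 3)
  expect_equal(nrow(res), 4)
  # max < min pairs and impossible minima fail; (40, 90) succeeds
  expect_equal(res$status[res$min_n == 40 & res$max_n == 90], "ok")
  expect_equal(res$status[res$min_n == 40 & res$max_n == 30], "failed")
  expect_equal(res$status[res$min_n == 200 & res$max_n == 90], "failed")
  best <- select_best(res)
  expect_equal(c(best$min_n, best$max_n), c(40, 90))
  g <- glance(res)
  expect_equal(g$n_failed, 3)
})

test_that("holdout error does not worsen as class separation grows", {
  mean_err <- vapply(c(1, 3, 6), function(sep) {
    errs <- vapply(1:5, function(s) {
      d <- gaussian_features(80, c("A", "B"), sep = sep, seed = s)
      train <- dplyr::filter(d, as.integer(sub(".*_", "", image_id)) <= 60)
      held <- dplyr::filter(d, as.integer(sub(".*_", "", image_id)) > 60)
      m <- train_forest(train, 25, seed = s)
      evaluate_candidate(m, held, vote_threshold = 0)$error_rate
    }, numeric(1))
    mean(errs)
  }, numeric(1))
  expect_true(all(diff(mean_err) <= 0.02)) # small statistical slack
})

test_that("verification schedules draw up to 3 samples per fortnight", {
  manifest <- tibble::tibble(
    sample_id = sprintf("s%03d", 1:42),
    time = as.POSIXct("2015-01-01", tz = "UTC") + (0:41) * 86400
  )
  ids <- verification_schedule(manifest, seed = 2)
  expect_length(ids, 9) # 3 windows x 3 samples
  expect_identical(ids, verification_schedule(manifest, seed = 2))

  sparse <- manifest[c(1:5, 40:41), ] # last window holds 2 samples
  ids2 <- verification_schedule(sparse, seed = 2)
  expect_length(ids2, 5)
  expect_length(verification_schedule(manifest[0, ]), 0)
})

test_that("verification comparison builds the right contingency", {
  auto <- tibble::tibble(image_id = sprintf("i%d", 1:6),
                         label = c("A", "A", "B", "B", "C", "C"))
  same <- verification_compare(auto, auto)
  expect_equal(sum(same$confusion), sum(diag(same$confusion)))
  expect_equal(same$agreement, 1)

  flipped <- dplyr::mutate(auto, label = c("D", "D", "E", "E", "F", "F"))
  vs <- verification_compare(auto, flipped)
  expect_equal(sum(diag(vs$confusion)), 0)
  expect_equal(vs$agreement, 0)
  td <- tidy(vs)
  expect_equal(sum(td$n), 6)

  expect_error(
    verification_compare(auto, dplyr::mutate(auto, image_id = paste0("x", image_id))),
    "same image set"
  )
})
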