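# Biovolume aggregation, smoothing, depth-frequency reporting.

mk_manifest <- function(n = 3, volume = 5, depth = 2) {
  tibble::tibble(
    sample_id = sprintf("s%02d", seq_len(n)),
    time = as.POSIXct("2015-01-01", tz = "UTC") + (seq_len(n) - 1) * 3600,
    depth_m = depth, volume_ml = volume
  )
}

test_that("aggregation divides class sums by the analysed volume", {
  manifest <- mk_manifest(2)
  recs <- tibble::tibble(
    sample_id = c("s01", "s01", "s02"),
    class = c("A", "A", "B"),
    biovolume_um3 = c(600, 400, 1000)
  )
  agg <- aggregate_biovolume(recs, manifest)
  expect_equal(
    agg$biovolume_um3_per_ml[agg$sample_id == "s01" & agg$class == "A"],
    200
  ) # 1000 um^3 / 5 mL
  # absent classes are explicit zeros; totals are conserved
  expect_equal(
    agg$biovolume_um3_per_ml[agg$sample_id == "s02" & agg$class == "A"],
    0
  )
  totals <- agg |>
    dplyr::group_by(sample_id) |>
    dplyr::summarise(tot = sum(biovolume_um3_per_ml))
  expect_equal(totals$tot, c(200, 200))

  expect_error(
    aggregate_biovolume(recs, dplyr::mutate(manifest, volume_ml = 0)),
    "positive"
  )
})

test_that("the small-image filter never increases a class series", {
  withr::with_seed(31, {
    manifest <- mk_manifest(5)
    recs <- tibble::tibble(
      sample_id = sample(manifest$sample_id, 200, replace = TRUE),
      class = sample(c("Urosolenia", "A"), 200, replace = TRUE),
      biovolume_um3 = rlnorm(200, log(80), 1)
    )
    before <- aggregate_biovolume(recs, manifest)
    after <- aggregate_biovolume(filter_small_images(recs), manifest,
                                 classes = sort(unique(recs$class)))
    merged <- dplyr::inner_join(before, after,
                                by = c("sample_id", "class"),
                                suffix = c("_b", "_a"))
    expect_true(all(merged$biovolume_um3_per_ml_a <=
                      merged$biovolume_um3_per_ml_b + 1e-12))
    expect_true(all(merged$biovolume_um3_per_ml_a[merged$class == "A"] ==
                      merged$biovolume_um3_per_ml_b[merged$class == "A"]))
  })
})

test_that("moving averages behave on constant, single and alternating series", {
  manifest <- mk_manifest(49)
  const <- tibble::tibble(
    sample_id = manifest$sample_id, class = "A",
    biovolume_um3 = 500
  )
  sm <- aggregate_biovolume(const, manifest) |> biovolume_moving_average()
  expect_equal(sm$smoothed_um3_per_ml, sm$biovolume_um3_per_ml)

  single <- aggregate_biovolume(const[1, ], manifest[1, ]) |>
    biovolume_moving_average()
  expect_equal(single$smoothed_um3_per_ml, single$biovolume_um3_per_ml)

  # alternating 0/2 at hourly spacing: interior +/-12 h windows hold 25
  # samples (13 of one parity, 12 of the other) -> means near 1
  alt <- tibble::tibble(
    sample_id = manifest$sample_id, class = "A",
    biovolume_um3 = rep(c(0, 10), length.out = 49)
  )
  sm2 <- aggregate_biovolume(alt, manifest) |> biovolume_moving_average()
  interior <- sm2$smoothed_um3_per_ml[13:37]
  expect_true(all(abs(interior - 1) <= 1 / 25 + 1e-9))
})

test_that("depth frequency reports the shallow-to-deep ratio", {
  cc <- campaign_config("2015-01-01", "2015-01-11",
                       depths_m = c(2, 4, 10, 15),
                       period_min = c(75, 75, 75, 375))
  camp <- generate_campaign(cc, taxa = default_taxa()[3], render = FALSE)
  rep <- depth_frequency_report(camp$manifest)
  expect_equal(nrow(rep$counts), 4)
  expect_lt(abs(rep$shallow_to_deep_ratio - 5), 0.5)

  single <- depth_frequency_report(mk_manifest(4))
  expect_true(is.na(single$shallow_to_deep_ratio))
  empty <- depth_frequency_report(mk_manifest(0))
  expect_equal(nrow(empty$counts), 0)
})

test_that("an imposed mid-season dip appears in the smoothed series", {
  # steady taxon with a 30% mid-season dip-and-recovery
  dipper <- taxon_model(
    "dipper", "needle", length_um = 40, width_um = 3,
    abundance = function(f) 25 * (1 - 0.3 * exp(-((f - 0.5) / 0.1)^2))
  )
  cc <- campaign_config("2015-01-01", "2015-01-31", depths_m = 2,
                       period_min = 180, rng_seed = 17)
  camp <- generate_campaign(cc, taxa = list(dipper = dipper),
                            render = FALSE)
  recs <- dplyr::transmute(camp$images, sample_id,
                           class = true_class,
                           biovolume_um3 = true_biovolume_um3)
  sm <- aggregate_biovolume(recs, camp$manifest) |>
    biovolume_moving_average()
  span_s <- as.numeric(difftime(cc$end, cc$start, units = "secs"))
  frac <- as.numeric(difftime(sm$time, cc$start, units = "secs")) / span_s
  central <- frac > 0.2 & frac < 0.8
  t_obs <- sm$time[central][which.min(sm$smoothed_um3_per_ml[central])]
  t_gen <- cc$start + 0.5 * span_s
  expect_lt(abs(as.numeric(difftime(t_obs, t_gen, units = "days"))), 3)
})
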