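# Synthetic ROI, campaign and profile generators.

test_that("ROI ground-truth biovolume is the analytic generative solid", {
  needle <- generate_roi(fixed_taxon(), seed = 1)
  expect_equal(needle$true_biovolume_um3, pi * 1.5^2 * 60, tolerance = 1e-3)

  disk <- generate_roi(fixed_taxon("r", "disk", length_um = 40), seed = 1)
  expect_equal(disk$true_biovolume_um3, 4 / 3 * pi * 20^3, tolerance = 1e-3)

  star <- generate_roi(
    fixed_taxon("a", "star_colony", length_um = 40, width_um = 3,
                colony_cells = 6L),
    seed = 1
  )
  expect_equal(star$true_biovolume_um3, 6 * pi * 1.5^2 * 40,
               tolerance = 1e-3)
})

test_that("frustule loss renders fragments but keeps the full biovolume", {
  uro <- fixed_taxon("u", "cylinder_with_chloroplasts",
                     length_um = 30, width_um = 7, frustule_loss_prob = 1)
  roi <- generate_roi(uro, seed = 2)
  expect_true(roi$fragment)
  expect_equal(roi$true_biovolume_um3, pi * 3.5^2 * 30, tolerance = 1e-3)
  mask <- segment_roi(roi$image)
  rendered <- estimate_biovolume(mask)
  expect_lt(rendered, roi$true_biovolume_um3)
  expect_lt(rendered, 61) # fragments fall under the small-image cut

  full <- generate_roi(fixed_taxon("u2", "cylinder_with_chloroplasts",
                                   length_um = 30, width_um = 7),
                       seed = 2)
  expect_false(full$fragment)
})

test_that("rendered particles are at least ~10 um unless fragments", {
  taxa <- default_taxa()
  withr::with_seed(7, {
    for (tx in taxa) {
      roi <- generate_roi(tx, frustule_loss = 0)
      mask <- segment_roi(roi$image)
      extent <- max(dim(mask)) # bounding box upper bound; check via mask
      idx <- which(mask == 1, arr.ind = TRUE)
      span <- max(diff(range(idx[, 1])), diff(range(idx[, 2])))
      expect_gte(span, 10)
    }
  })
})

test_that("sample schedule drops the last partial interval", {
  cc <- campaign_config("2015-01-01", "2015-01-02", depths_m = 2,
                       period_min = 25)
  camp <- generate_campaign(cc, taxa = default_taxa()[1], render = FALSE)
  # enumeration: k*25-min intervals fitting in 1440 min -> 57 samples
  expect_equal(nrow(camp$manifest), 57)
  expect_equal(camp$manifest$time[1], cc$start)
})

test_that("campaigns are deterministic and conserve ground truth", {
  cc <- campaign_config("2015-01-01", "2015-01-02", depths_m = c(2, 10),
                       period_min = c(360, 720), rng_seed = 11)
  c1 <- generate_campaign(cc, render = TRUE)
  c2 <- generate_campaign(cc, render = TRUE)
  expect_identical(c1$manifest, c2$manifest)
  expect_identical(c1$images, c2$images)
  # every emitted image has exactly one ground-truth row
  expect_equal(length(c1$images$image), nrow(c1$images))
  expect_equal(anyDuplicated(c1$images$image_id), 0)
})

test_that("zero-abundance taxa produce no images", {
  ghost <- taxon_model("ghost", "needle", 30, abundance = function(t) 0)
  cc <- campaign_config("2015-01-01", "2015-01-02", depths_m = 2,
                       period_min = 120, rng_seed = 3)
  camp <- generate_campaign(cc, taxa = list(ghost = ghost), render = FALSE)
  expect_equal(nrow(camp$images), 0)
})

test_that("the flash step multiplies fragment captures only", {
  uro <- taxon_model("Urosolenia", "cylinder_with_chloroplasts",
                     length_um = 30, width_um = 7,
                     frustule_loss_prob = 0.2,
                     abundance = function(t) 30)
  cc <- campaign_config("2015-01-01", "2015-01-11", depths_m = 2,
                       period_min = 240, rng_seed = 5,
                       flash_step_time = "2015-01-06",
                       flash_step_factor = 4)
  camp <- generate_campaign(cc, taxa = list(Urosolenia = uro),
                            render = FALSE)
  imgs <- dplyr::mutate(camp$images, after = time >= cc$flash_step_time)
  frac <- imgs |>
    dplyr::group_by(after) |>
    dplyr::summarise(frag = mean(fragment), n_full = sum(!fragment),
                     n_samp = dplyr::n_distinct(sample_id))
  # fragment share jumps ~(0.2 -> 0.5); full-image rate is unchanged
  expect_gt(frac$frag[frac$after], 2 * frac$frag[!frac$after])
  full_rate <- frac$n_full / frac$n_samp
  expect_lt(abs(full_rate[2] - full_rate[1]) / full_rate[1], 0.35)
})

test_that("config validation rejects degenerate campaigns", {
  expect_error(campaign_config("2015-01-02", "2015-01-01"), "after")
  expect_error(campaign_config("2015-01-01", "2015-01-02",
                               depths_m = c(4, 2)), "ascending")
  expect_error(campaign_config("2015-01-01", "2015-01-02",
                               syringe_volume_ml = 0), "positive")
  expect_error(taxon_model("x", "needle", -3), "positive")
  expect_error(taxon_model("x", "needle", 30, frustule_loss_prob = 1.2),
               "\\[0, 1\\]")
})

test_that("scenario profiles have the advertised structure", {
  times <- as.POSIXct(c("2015-02-15 00:00", "2015-02-15 12:00"), tz = "UTC")

  # isothermal: density gradient below threshold everywhere
  iso <- generate_profiles(scenario_config("isothermal_autumn"), times)
  rho <- density_profile(dplyr::filter(iso, time == times[1]))
  expect_lt(max(abs(diff(rho$rho_kg_m3) / diff(rho$depth_m))), 0.01)

  # stable winter at night: no light at any depth
  sw <- generate_profiles(scenario_config("stable_winter"), times)
  night <- dplyr::filter(sw, time == times[1])
  q <- solar_radiation_at_depth(night)
  expect_true(all(q$q_w_m2 == 0))

  # monotone inverse stratification -> density increasing with depth
  rho_sw <- density_profile(night)
  expect_true(all(diff(rho_sw$rho_kg_m3) > 0))
  expect_true(all(night$temp_c < 4))
  expect_true(!is.unsorted(night$temp_c))
})
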