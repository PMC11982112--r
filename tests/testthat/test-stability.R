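# Solar radiation at depth, stable-layer detection, Richardson diagnosis.

test_that("solar radiation integrates the PAR band and divides by 0.75", {
  prof <- tibble::tibble(depth_m = c(1, 2))
  for (l in c(398.76, 500, 600, 700.04)) prof[[paste0("ed_", l)]] <- 1
  q <- solar_radiation_at_depth(prof)
  # flat 1 uW cm^-2 nm^-1 over 301.28 nm: planar 3.0128 W m^-2, scalar /0.75
  expect_equal(q$q_w_m2, rep(3.0128 / 0.75, 2), tolerance = 1e-10)

  prof0 <- dplyr::mutate(prof, dplyr::across(dplyr::starts_with("ed_"), ~0))
  expect_true(all(solar_radiation_at_depth(prof0)$q_w_m2 == 0))

  decay <- convective_test_profile(ed_value = 10)
  for (l in c(398.76, 500, 600, 700.04)) {
    decay[[paste0("ed_", l)]] <- 10 * exp(-0.5 * decay$depth_m)
  }
  qd <- solar_radiation_at_depth(decay)
  expect_true(all(diff(qd$q_w_m2) < 0))

  expect_error(solar_radiation_at_depth(tibble::tibble(depth_m = 1:3)),
               "spectral")
})

test_that("stable-layer detection applies the gradient criterion", {
  z <- seq(1, 10, by = 0.5)

  uniform <- tibble::tibble(depth_m = z, rho_kg_m3 = rep(1000, length(z)))
  expect_true(is.na(detect_stable_surface_layer(uniform)))

  # 0.02 kg m^-4 over the top 2 m then uniform -> h = 2.0
  rho <- 1000 + 0.02 * pmin(z - 1, 2)
  layered <- tibble::tibble(depth_m = z, rho_kg_m3 = rho)
  expect_equal(detect_stable_surface_layer(layered), 2.0)

  # first interval below threshold -> no layer even if deeper ones pass
  rho2 <- 1000 + c(0, 0.0025, cumsum(rep(0.02, length(z) - 2)) + 0.0025)
  first_fail <- tibble::tibble(depth_m = z, rho_kg_m3 = rho2)
  expect_true(is.na(detect_stable_surface_layer(first_fail)))

  expect_warning(
    out <- detect_stable_surface_layer(uniform[1, ]),
    "Fewer than 2"
  )
  expect_true(is.na(out))
})

test_that("raising the stability threshold never deepens the layer", {
  withr::with_seed(42, {
    for (i in 1:5) {
      z <- seq(0.5, 15, by = 0.5)
      rho <- 1000 + cumsum(abs(rnorm(length(z), 0.005, 0.01)))
      tb <- tibble::tibble(depth_m = z, rho_kg_m3 = rho)
      hs <- vapply(c(0.005, 0.01, 0.02, 0.05),
                   function(th) detect_stable_surface_layer(tb, th),
                   numeric(1))
      hs[is.na(hs)] <- 0
      expect_true(all(diff(hs) <= 0))
    }
  })
})

test_that("a hand-computed clear-ice case is diagnosed convective", {
  prof <- convective_test_profile(ed_value = 150)
  rho <- density_profile(prof, salinity_ref = 0.03)
  h <- detect_stable_surface_layer(rho)
  expect_equal(h, 1.5)
  d <- richardson_diagnosis(prof, h, salinity_ref = 0.03)

  # independent hand computation from the exported primitives
  q <- 150 * (700.04 - 398.76) * 1e-2 / 0.75
  i <- which(rho$depth_m == 2)
  alpha <- thermal_expansibility(rho$temp_c[i], rho$salinity_g_l[i], 2)
  b <- -9.81 * alpha * q /
    (rho$rho_kg_m3[i] * specific_heat(rho$temp_c[i], rho$salinity_g_l[i]))
  w_star <- (b * h)^(1 / 3)
  n2 <- 9.81 / rho$rho_kg_m3[i] *
    (rho$rho_kg_m3[i + 1] - rho$rho_kg_m3[i]) / 0.5
  ri <- n2 * h^2 / w_star^2

  expect_equal(d$q_w_m2, q, tolerance = 1e-6)
  expect_equal(d$b_m2_s3, b, tolerance = 1e-6)
  expect_equal(d$w_star_m_s, w_star, tolerance = 1e-6)
  expect_equal(d$ri, ri, tolerance = 1e-6)
  expect_gt(d$b_m2_s3, 0)
  expect_lte(d$ri, 1)
  expect_true(d$convective)
})

test_that("removing any convection precondition flips the flag", {
  base <- convective_test_profile(ed_value = 150)
  h <- 1.5

  # darkness: Q = 0 -> b = 0
  dark <- dplyr::mutate(base, dplyr::across(dplyr::starts_with("ed_"), ~0))
  d_dark <- richardson_diagnosis(dark, h, salinity_ref = 0.03)
  expect_equal(d_dark$b_m2_s3, 0)
  expect_false(d_dark$convective)

  # warm water at the test depth: alpha > 0 -> b < 0
  warm <- dplyr::mutate(base, temp_c = temp_c + 3) # test depth ~6.2 degC
  d_warm <- richardson_diagnosis(warm, h, salinity_ref = 0.03)
  expect_lt(d_warm$b_m2_s3, 0)
  expect_false(d_warm$convective)

  # strong stratification below the layer: Ri > 1
  strat <- dplyr::mutate(
    base, temp_c = ifelse(depth_m > 2, 3.2 + 0.45 * (depth_m - 2), temp_c)
  )
  d_strat <- richardson_diagnosis(strat, h, salinity_ref = 0.03)
  expect_gt(d_strat$ri, 1)
  expect_false(d_strat$convective)

  expect_error(richardson_diagnosis(base, NA_real_), "detect")
})

test_that("season diagnosis reproduces the scenario contracts", {
  times <- as.POSIXct(paste0("2015-02-1", 0:3, " 12:00:00"), tz = "UTC")
  times <- sort(c(times, times - 12 * 3600))

  sw <- season_diagnosis(generate_profiles(scenario_config("stable_winter"),
                                           times))
  expect_true(all(!is.na(sw$h_m)))
  expect_true(all(!sw$convective))

  ci <- season_diagnosis(
    generate_profiles(scenario_config("clear_ice_heating"), times)
  )
  expect_gte(sum(ci$convective), 1)

  iso <- season_diagnosis(
    generate_profiles(scenario_config("isothermal_autumn"), times)
  )
  expect_true(all(is.na(iso$h_m)))
  expect_true(all(!iso$convective))
})
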