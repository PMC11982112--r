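# Stable-surface-layer detection and the Richardson-number diagnosis of
# radiatively driven convection under ice.
#
# Under snow-free, clear ice, sunlight can heat water that is below the
# temperature of maximum density; the heated water densifies (alpha < 0)
# and sinks, driving convection beneath any stable surface layer. The
# diagnosis computes, per profile: density and its gradient at 0.5-m
# intervals, the stable-surface-layer thickness h, the buoyancy flux
# b = g * alpha * Q / (rho * c_p) (signed so b > 0 when cold-water
# heating is convection-driving), the convective velocity
# w* = (b * h)^(1/3), the buoyancy frequency N^2 = (g / rho) * drho/dz of
# the stratification at the convective test depth (base of the stable
# layer), and the Richardson number Ri = N^2 h^2 / w*^2. A convective
# mixed layer is diagnosed iff Ri <= 1 and b > 0.

.g <- 9.81 # m s^-2

#' Solar radiation at depth from spectral irradiance
#'
#' Band-integrates spectral planar downwelling irradiance over the PAR
#' band (trapezoid rule over the `ed_<nm>` columns, uW cm^-2 nm^-1 to
#' W m^-2) and divides by 0.75 to approximate scalar irradiance.
#'
#' @param profile One profile: tibble with `depth_m` and `ed_<nm>`
#'   columns (a single time).
#' @param scalar_divisor Planar-to-scalar conversion divisor.
#' @return Tibble with `depth_m` and `q_w_m2` (scalar irradiance, W m^-2).
#' @export
solar_radiation_at_depth <- function(profile, scalar_divisor = 0.75) {
  lambda <- ed_wavelengths(profile)
  if (length(lambda) < 2) {
    abort("Profile lacks spectral irradiance columns (`ed_<nm>`).")
  }
  ord <- order(lambda)
  lambda <- lambda[ord]
  ed <- as.matrix(profile[paste0("ed_", lambda)])
  if (any(ed < 0, na.rm = TRUE)) abort("Irradiance must be non-negative.")
  dl <- diff(lambda)
  # trapezoid over wavelength, per depth row
  planar_uw_cm2 <- as.vector((ed[, -ncol(ed), drop = FALSE] +
                                ed[, -1, drop = FALSE]) %*% dl) / 2
  tibble(
    depth_m = profile$depth_m,
    q_w_m2 = planar_uw_cm2 * 1e-2 / scalar_divisor
  )
}

#' Density profile on a regular grid
#'
#' Computes density at the observed depths from temperature and salinity
#' (volumetric salinity scaled along the conductivity profile), then
#' linearly resamples to `dz` intervals starting at the first valid
#' depth. By default the pressure term is zeroed (potential density
#' referenced to the surface): at lake depths the compressibility
#' contribution to the in-situ gradient (~0.005 kg m^-4) is comparable
#' to the stability threshold yet carries no stratification, so
#' stability tests must not see it.
#'
#' @param profile One profile (tibble with `depth_m`, `temp_c`,
#'   `cond_s_m`, `pres_dbar`).
#' @param salinity_ref Volumetric salinity (g/L) at the reference
#'   conductivity, e.g. from [volumetric_salinity()].
#' @param dz Resampling interval, m.
#' @param potential Use potential density (p = 0); `FALSE` gives
#'   in-situ density from the `pres_dbar` column.
#' @return Tibble with `depth_m`, `temp_c`, `salinity_g_l`, `rho_kg_m3`.
#' @export
density_profile <- function(profile, salinity_ref = volumetric_salinity(),
                            dz = 0.5, potential = TRUE) {
  stopifnot(all(c("depth_m", "temp_c") %in% names(profile)))
  prof <- dplyr::arrange(profile, .data$depth_m)
  cond <- if ("cond_s_m" %in% names(prof)) prof$cond_s_m else NULL
  sal <- if (!is.null(cond) && mean(cond) > 0) {
    salinity_ref * cond / mean(cond)
  } else {
    rep(salinity_ref, nrow(prof))
  }
  pres <- if ("pres_dbar" %in% names(prof)) prof$pres_dbar else prof$depth_m
  grid <- seq(min(prof$depth_m), max(prof$depth_m), by = dz)
  t_g <- approx(prof$depth_m, prof$temp_c, grid)$y
  s_g <- approx(prof$depth_m, sal, grid)$y
  p_g <- if (potential) 0 * grid else approx(prof$depth_m, pres, grid)$y
  tibble(
    depth_m = grid, temp_c = t_g, salinity_g_l = s_g,
    rho_kg_m3 = water_density(t_g, s_g, p_g)
  )
}

#' Detect a stable surface layer
#'
#' Tests density gradients at `dz` intervals, starting at the first
#' valid depth, against the stability criterion: an interval is stable
#' iff its gradient exceeds `threshold` (0.01 kg m^-4 by default). The
#' layer thickness `h` is the extent of the maximal contiguous stable
#' run starting at the first interval; if the very first interval fails
#' the criterion, no stable surface layer is diagnosed.
#'
#' @param rho Tibble from [density_profile()] (`depth_m`, `rho_kg_m3`),
#'   already on the regular grid.
#' @param threshold Stability threshold on the density gradient,
#'   kg m^-4.
#' @return Thickness `h` in metres, or `NA_real_` when no stable surface
#'   layer is present.
#' @export
detect_stable_surface_layer <- function(rho, threshold = 0.01) {
  if (nrow(rho) < 2) {
    warn("Fewer than 2 valid depths; no layer can be diagnosed.")
    return(NA_real_)
  }
  grad <- diff(rho$rho_kg_m3) / diff(rho$depth_m)
  stable <- grad > threshold
  if (!stable[1]) return(NA_real_)
  run_end <- if (all(stable)) length(stable) else which(!stable)[1] - 1
  rho$depth_m[run_end + 1] - rho$depth_m[1]
}

#' Richardson-number convection diagnosis for one profile
#'
#' Requires a previously detected stable surface layer of thickness `h`.
#' The convective test depth is the base of that layer. Computes, at
#' the test depth: scalar solar radiation Q (interpolated from
#' [solar_radiation_at_depth()]), thermal expansibility and specific
#' heat, buoyancy flux `b = g * alpha * Q / (rho * c_p)` (signed
#' convection-positive: heating below the density maximum gives b > 0),
#' convective velocity `w* = (b h)^(1/3)` for b > 0 (else 0), the
#' buoyancy frequency squared `N^2` from the density gradient of the
#' first interval below the layer base (the stratification convection
#' must erode; floored at 0), and `Ri = N^2 h^2 / w*^2` (infinite when
#' w* = 0). Convective iff `Ri <= 1` and `b > 0`.
#'
#' @param profile One profile (single time) with `depth_m`, `temp_c`,
#'   `cond_s_m`, `pres_dbar`, `ed_<nm>` columns.
#' @param h Stable-surface-layer thickness (m); see
#'   [detect_stable_surface_layer()]. Must be present (call detection
#'   first).
#' @param salinity_ref Volumetric salinity at reference conductivity, g/L.
#' @param threshold Stability-criterion threshold, kg m^-4.
#' @param dz Gradient interval, m.
#' @return One-row tibble with columns `h_m`, `test_depth_m`,
#'   `temp_test_c`, `alpha_per_c`, `cp_j_kg_c`, `q_w_m2`, `b_m2_s3`,
#'   `w_star_m_s`, `n2_s2`, `ri`, `convective`, plus a `rho` list-column
#'   holding the gridded density profile.
#' @export
richardson_diagnosis <- function(profile, h,
                                 salinity_ref = volumetric_salinity(),
                                 threshold = 0.01, dz = 0.5) {
  if (is.null(h) || is.na(h)) {
    abort("`h` is missing: detect a stable surface layer first.")
  }
  rho <- density_profile(profile, salinity_ref, dz)
  test_depth <- rho$depth_m[1] + h
  i_base <- which.min(abs(rho$depth_m - test_depth))

  qz <- solar_radiation_at_depth(profile)
  q_test <- approx(qz$depth_m, qz$q_w_m2, test_depth, rule = 2)$y

  t_test <- rho$temp_c[i_base]
  s_test <- rho$salinity_g_l[i_base]
  rho_test <- rho$rho_kg_m3[i_base]
  alpha <- thermal_expansibility(t_test, s_test, test_depth)
  cp <- specific_heat(t_test, s_test)

  # convection-positive sign: alpha < 0 with Q > 0 gives b > 0
  b <- -.g * alpha * q_test / (rho_test * cp)
  w_star <- if (b > 0) (b * h)^(1 / 3) else 0

  # stratification at the test depth: first interval below the layer base
  if (i_base < nrow(rho)) {
    grad_below <- (rho$rho_kg_m3[i_base + 1] - rho$rho_kg_m3[i_base]) /
      (rho$depth_m[i_base + 1] - rho$depth_m[i_base])
  } else {
    grad_below <- (rho$rho_kg_m3[i_base] - rho$rho_kg_m3[i_base - 1]) /
      (rho$depth_m[i_base] - rho$depth_m[i_base - 1])
  }
  n2 <- .g / rho_test * max(grad_below, 0)
  ri <- if (w_star > 0) n2 * h^2 / w_star^2 else Inf
  tibble(
    h_m = h, test_depth_m = test_depth, temp_test_c = t_test,
    alpha_per_c = alpha, cp_j_kg_c = cp, q_w_m2 = q_test,
    b_m2_s3 = b, w_star_m_s = w_star, n2_s2 = n2, ri = ri,
    convective = ri <= 1 && b > 0,
    rho = list(rho)
  )
}

#' Stability and convection diagnosis for a profile time series
#'
#' Runs [density_profile()], [detect_stable_surface_layer()] and (when a
#' layer is present) [richardson_diagnosis()] for every profile time.
#'
#' @param profiles Long profile tibble (multiple times) as produced by
#'   [generate_profiles()] or read from CSV.
#' @param salinity_ref Volumetric salinity at reference conductivity, g/L.
#' @param threshold Stability threshold, kg m^-4.
#' @param dz Gradient interval, m.
#' @return Tibble with one row per profile time: `time`, `h_m` (NA when
#'   no stable layer), the diagnosis columns of [richardson_diagnosis()]
#'   (NA without a layer), and `convective` (FALSE without a layer).
#' @export
season_diagnosis <- function(profiles, salinity_ref = volumetric_salinity(),
                             threshold = 0.01, dz = 0.5) {
  profiles |>
    dplyr::group_by(.data$time) |>
    dplyr::group_modify(function(prof, key) {
      rho <- density_profile(prof, salinity_ref, dz)
      h <- detect_stable_surface_layer(rho, threshold)
      if (is.na(h)) {
        return(tibble(h_m = NA_real_, convective = FALSE))
      }
      diag <- richardson_diagnosis(prof, h, salinity_ref, threshold, dz)
      dplyr::select(diag, -"rho")
    }) |>
    dplyr::ungroup()
}
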