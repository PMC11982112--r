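# Synthetic environmental profiles: temperature, conductivity, pressure
# and spectral downwelling irradiance on a depth grid, per scenario.

# Wavelength grid for the PAR band (nm); endpoints define the band and
# 490 nm is carried explicitly as the irradiance-plot channel.
.par_wavelengths <- function() {
  sort(unique(c(398.76, seq(420, 680, by = 20), 490, 700.04)))
}

.temp_profile <- function(scenario, z) {
  with(scenario, switch(scenario,
    stable_winter =
      bottom_temp_c - (bottom_temp_c - surface_temp_c) *
        exp(-z / transition_depth_m),
    clear_ice_heating = {
      t_base <- bottom_temp_c -
        deep_gradient_c_per_m * (17.5 - transition_depth_m)
      ifelse(
        z <= transition_depth_m,
        surface_temp_c + (t_base - surface_temp_c) * z / transition_depth_m,
        t_base + deep_gradient_c_per_m * (z - transition_depth_m)
      )
    },
    isothermal_autumn = rep(surface_temp_c, length(z))
  ))
}

.seasonal_factor <- function(scenario, time) {
  if (is.null(scenario$season_range)) return(1)
  frac <- .season_frac(time, scenario$season_range[1],
                       scenario$season_range[2])
  frac <- pmin(pmax(frac, 0), 1)
  1 - 0.8 * exp(-((frac - 0.55) / 0.25)^2)
}

.diel_factor <- function(time) {
  hod <- as.numeric(format(time, "%H")) + as.numeric(format(time, "%M")) / 60
  pmax(0, sin(pi * (hod - 7) / 10))
}

# surface spectrum shape, peaked near 490 nm
.spectrum_shape <- function(lambda) exp(-((lambda - 490) / 180)^2)

#' Generate environmental profiles for a scenario
#'
#' Evaluates the scenario's temperature, conductivity and spectral
#' irradiance fields at the given times over a depth grid. Temperature
#' and conductivity are static (winter water columns evolve over weeks,
#' not hours); irradiance carries the diel cycle, the snow/ice
#' transmittance, exponential attenuation with depth, and -- when the
#' scenario has a `season_range` -- a seasonal envelope with a
#' late-winter minimum. The output is deterministic.
#'
#' @param scenario A [scenario_config()].
#' @param times POSIXct vector of profile times, sorted ascending.
#' @param depths_m Depth grid, m (strictly increasing, positive down).
#' @return Long tibble with one row per (time, depth): columns `time`,
#'   `depth_m`, `temp_c`, `cond_s_m`, `pres_dbar`, and one `ed_<nm>`
#'   column per wavelength (uW cm^-2 nm^-1).
#' @export
generate_profiles <- function(scenario, times,
                              depths_m = seq(0.5, 17.5, by = 0.5)) {
  if (!inherits(scenario, "scenario_config")) {
    abort("`scenario` must be a scenario_config.")
  }
  times <- as.POSIXct(times, tz = "UTC")
  if (is.unsorted(times)) abort("`times` must be sorted ascending.")
  if (is.unsorted(depths_m, strictly = TRUE)) {
    abort("`depths_m` must be strictly increasing.")
  }
  lambda <- .par_wavelengths()
  shape <- .spectrum_shape(lambda)
  purrr::map_dfr(times, function(tm) {
    surf <- scenario$ed_peak * .diel_factor(tm) *
      .seasonal_factor(scenario, tm) * scenario$cover_transmittance
    ed <- outer(exp(-scenario$kd_par * depths_m), surf * shape)
    colnames(ed) <- paste0("ed_", lambda)
    dplyr::bind_cols(
      tibble(
        time = tm, depth_m = depths_m,
        temp_c = .temp_profile(scenario, depths_m),
        cond_s_m = scenario$cond_base_s_m *
          (1 + scenario$cond_gradient_per_m * depths_m),
        pres_dbar = depths_m
      ),
      as_tibble(ed)
    )
  })
}

#' Wavelengths of the irradiance columns of a profile table
#'
#' @param profile Data frame with `ed_<nm>` columns.
#' @return Numeric vector of wavelengths (nm), in column order.
#' @export
ed_wavelengths <- function(profile) {
  nm <- grep("^ed_", names(profile), value = TRUE)
  as.numeric(sub("^ed_", "", nm))
}
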