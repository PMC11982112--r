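# Campaign and scenario configuration objects.

#' Configure a synthetic sampling campaign
#'
#' Describes the sampling geometry of a winter deployment: a profiling
#' winch positions the imaging flow cytometer at a fixed set of depths,
#' drawing one syringe sample per visit. Shallow depths are sampled
#' about five times more often than the deepest one; the overall cadence
#' works out to roughly one sample per 25 minutes.
#'
#' Sample times at a depth start at the campaign start and recur every
#' period; a final sample whose period does not fit entirely before the
#' campaign end is dropped.
#'
#' @param start,end Campaign start/end (POSIXct, or anything
#'   `as.POSIXct()` accepts; UTC assumed).
#' @param depths_m Sampling depths in metres, strictly ascending.
#' @param period_min Per-depth sampling period in minutes (recycled).
#' @param syringe_volume_ml Analysed volume per sample, mL.
#' @param flash_step_time Optional timestamp after which the rendered
#'   chloroplast-fragment frequency is multiplied by `flash_step_factor`
#'   (emulating a mid-deployment flash-lamp intensity change).
#' @param flash_step_factor Multiplier on the frustule-loss probability
#'   after `flash_step_time`.
#' @param rng_seed Integer seed making the campaign reproducible.
#' @return A `campaign_config` object.
#' @export
campaign_config <- function(start, end,
                            depths_m = c(2, 4, 10, 15),
                            period_min = c(75, 75, 75, 375),
                            syringe_volume_ml = 5,
                            flash_step_time = NULL,
                            flash_step_factor = 3,
                            rng_seed = 1L) {
  start <- as.POSIXct(start, tz = "UTC")
  end <- as.POSIXct(end, tz = "UTC")
  if (end <= start) abort("`end` must be after `start`.")
  if (is.unsorted(depths_m, strictly = TRUE)) {
    abort("`depths_m` must be strictly ascending.")
  }
  period_min <- rep_len(period_min, length(depths_m))
  if (any(period_min <= 0)) abort("`period_min` must be positive.")
  if (syringe_volume_ml <= 0) abort("`syringe_volume_ml` must be positive.")
  if (!is.null(flash_step_time)) {
    flash_step_time <- as.POSIXct(flash_step_time, tz = "UTC")
  }
  if (flash_step_factor < 0) abort("`flash_step_factor` must be >= 0.")
  structure(
    list(
      start = start, end = end, depths_m = depths_m,
      period_min = period_min, syringe_volume_ml = syringe_volume_ml,
      flash_step_time = flash_step_time,
      flash_step_factor = flash_step_factor,
      rng_seed = as.integer(rng_seed)
    ),
    class = "campaign_config"
  )
}

#' Configure an environmental scenario
#'
#' Three idealised hydrographic regimes, designed so that the mixing
#' diagnosis has both of its outcomes exercised:
#'
#' * `stable_winter` -- snow-covered ice, inverse thermal stratification
#'   (cold light water over ~3.5 degC water near the sediments), very weak
#'   irradiance: stable surface layers are present but radiative forcing
#'   is never close to overturning them.
#' * `clear_ice_heating` -- a thin, sharp meltwater-like stable layer
#'   over a nearly isothermal cold column, with strong light through
#'   clear ice: midday heating below the layer drives convection.
#' * `isothermal_autumn` -- a uniform water column above the density
#'   maximum; no stable surface layer at all.
#'
#' @param scenario One of `stable_winter`, `clear_ice_heating`,
#'   `isothermal_autumn`.
#' @param surface_temp_c,bottom_temp_c Temperature endpoints, degC,
#'   within `[0, 30]`.
#' @param transition_depth_m Depth scale of the near-surface thermal
#'   transition, m.
#' @param deep_gradient_c_per_m Residual deep temperature gradient for
#'   `clear_ice_heating`, degC per m.
#' @param cond_base_s_m Surface specific conductivity, S/m.
#' @param cond_gradient_per_m Fractional conductivity increase per metre.
#' @param ed_peak Spectral downwelling irradiance scale just below the
#'   surface at midday before cover attenuation, uW cm^-2 nm^-1.
#' @param cover_transmittance Snow/ice transmittance factor in `[0, 1]`.
#' @param kd_par Diffuse attenuation coefficient for the PAR band, m^-1.
#' @param season_range Optional POSIXct length-2 vector; when given, a
#'   seasonal envelope (late-winter minimum) modulates surface
#'   irradiance over this range.
#' @return A `scenario_config` object.
#' @export
scenario_config <- function(scenario = c("stable_winter", "clear_ice_heating",
                                         "isothermal_autumn"),
                            surface_temp_c = NULL, bottom_temp_c = NULL,
                            transition_depth_m = NULL,
                            deep_gradient_c_per_m = 0.003,
                            cond_base_s_m = 0.005,
                            cond_gradient_per_m = NULL,
                            ed_peak = NULL, cover_transmittance = NULL,
                            kd_par = 0.5, season_range = NULL) {
  scenario <- match.arg(scenario)
  defaults <- switch(scenario,
    stable_winter = list(
      surface_temp_c = 0.8, bottom_temp_c = 3.5, transition_depth_m = 2,
      cond_gradient_per_m = 0.01, ed_peak = 120, cover_transmittance = 0.02
    ),
    clear_ice_heating = list(
      surface_temp_c = 0.5, bottom_temp_c = 3.2, transition_depth_m = 2,
      cond_gradient_per_m = 0, ed_peak = 165, cover_transmittance = 0.35
    ),
    isothermal_autumn = list(
      surface_temp_c = 6, bottom_temp_c = 6, transition_depth_m = 2,
      cond_gradient_per_m = 0, ed_peak = 150, cover_transmittance = 0.5
    )
  )
  cfg <- list(
    scenario = scenario,
    surface_temp_c = surface_temp_c %||% defaults$surface_temp_c,
    bottom_temp_c = bottom_temp_c %||% defaults$bottom_temp_c,
    transition_depth_m = transition_depth_m %||% defaults$transition_depth_m,
    deep_gradient_c_per_m = deep_gradient_c_per_m,
    cond_base_s_m = cond_base_s_m,
    cond_gradient_per_m = cond_gradient_per_m %||% defaults$cond_gradient_per_m,
    ed_peak = ed_peak %||% defaults$ed_peak,
    cover_transmittance = cover_transmittance %||% defaults$cover_transmittance,
    kd_par = kd_par,
    season_range = if (!is.null(season_range)) {
      as.POSIXct(season_range, tz = "UTC")
    }
  )
  if (cfg$surface_temp_c < 0 || cfg$surface_temp_c > 30 ||
      cfg$bottom_temp_c < 0 || cfg$bottom_temp_c > 30) {
    abort("Scenario temperatures must lie within [0, 30] degC.")
  }
  if (cfg$ed_peak < 0) abort("`ed_peak` must be non-negative.")
  if (cfg$cover_transmittance < 0 || cfg$cover_transmittance > 1) {
    abort("`cover_transmittance` must be in [0, 1].")
  }
  structure(cfg, class = "scenario_config")
}

#' Read or write configuration objects as YAML
#'
#' @param config A `campaign_config` or `scenario_config`.
#' @param path File path.
#' @return `write_config()` returns `path` invisibly; `read_config()`
#'   returns the reconstructed config object.
#' @export
write_config <- function(config, path) {
  rlang::check_installed("yaml")
  kind <- class(config)[1]
  x <- unclass(config)
  x$abundance <- NULL
  x <- lapply(x, function(v) {
    if (inherits(v, "POSIXct")) format(v, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
    else v
  })
  yaml::write_yaml(c(list(kind = kind), x), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  rlang::check_installed("yaml")
  x <- yaml::read_yaml(path)
  kind <- x$kind
  x$kind <- NULL
  if (identical(kind, "campaign_config")) {
    do.call(campaign_config, x)
  } else if (identical(kind, "scenario_config")) {
    if (!is.null(x$season_range)) {
      x$season_range <- as.POSIXct(x$season_range, tz = "UTC")
    }
    do.call(scenario_config, x)
  } else {
    abort("Unrecognised config kind in YAML file.")
  }
}
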