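# Profile QC and time-depth section gridding.
#
# Profiles arrive at irregular times (the winch worked when it felt like
# it); all environmental variables are interpolated onto a fine fixed
# grid: depths 0-18.5 m at 0.1 m, times at 20-min steps, with a 6-h cap
# on the interpolation interval so winch outages are masked rather than
# bridged.

#' Quality-control raw profiles
#'
#' Drops, with logged reasons: empty profiles, profiles whose depth
#' records are not strictly increasing, and profiles containing
#' out-of-physical-range values (temperature outside (-1, 35) degC,
#' negative conductivity or irradiance).
#'
#' @param profiles Long tibble with `time`, `depth_m`, `temp_c` and
#'   optionally `cond_s_m` and `ed_<nm>` columns.
#' @return List with `profiles` (clean rows) and `log` (tibble `time`,
#'   `status`, `reason`).
#' @export
qc_profiles <- function(profiles) {
  profiles <- as_tibble(profiles)
  times <- unique(profiles$time)
  ed_cols <- grep("^ed_", names(profiles), value = TRUE)
  verdict <- purrr::map_dfr(times, function(tm) {
    prof <- profiles[profiles$time == tm, ]
    reason <- if (nrow(prof) == 0 || all(is.na(prof$temp_c))) {
      "empty"
    } else if (is.unsorted(prof$depth_m, strictly = TRUE)) {
      "non-monotone depth"
    } else if (any(prof$temp_c <= -1 | prof$temp_c >= 35, na.rm = TRUE)) {
      "temperature out of range"
    } else if ("cond_s_m" %in% names(prof) &&
               any(prof$cond_s_m < 0, na.rm = TRUE)) {
      "negative conductivity"
    } else if (length(ed_cols) > 0 &&
               any(as.matrix(prof[ed_cols]) < 0, na.rm = TRUE)) {
      "negative irradiance"
    } else {
      NA_character_
    }
    tibble(time = tm, status = ifelse(is.na(reason), "pass", "reject"),
           reason = reason)
  })
  keep <- verdict$time[verdict$status == "pass"]
  list(
    profiles = profiles[profiles$time %in% keep, ],
    log = verdict
  )
}

#' Fill irradiance gaps within a profile
#'
#' Regresses the natural log of the positive irradiance values on depth
#' and replaces missing values with the exponentiated fit -- the
#' log-linear model appropriate for exponentially attenuated light.
#' Observed values are never overwritten. With fewer than two positive
#' observations the profile is returned unfilled with a warning.
#'
#' @param profile One profile (single time).
#' @param column Irradiance column to fill (default: the 490-nm channel
#'   if present, else the first `ed_` column).
#' @return The profile with gaps in `column` filled.
#' @export
fill_irradiance_gaps <- function(profile, column = NULL) {
  ed_cols <- grep("^ed_", names(profile), value = TRUE)
  if (is.null(column)) {
    column <- if ("ed_490" %in% ed_cols) "ed_490" else ed_cols[1]
  }
  if (is.null(column) || !column %in% names(profile)) {
    abort("No irradiance column found to fill.")
  }
  y <- profile[[column]]
  obs <- !is.na(y) & y > 0
  if (sum(obs) < 2) {
    warn("Fewer than 2 positive irradiance values; profile left unfilled.")
    return(profile)
  }
  fit <- stats::lm(log(y[obs]) ~ profile$depth_m[obs])
  miss <- is.na(y)
  if (any(miss)) {
    pred <- fit$coefficients[1] + fit$coefficients[2] * profile$depth_m[miss]
    profile[[column]][miss] <- exp(pred)
  }
  profile
}

#' Build a time-depth section for one variable
#'
#' Each profile is first linearly interpolated in depth onto the 0.1-m
#' grid (masked outside its observed depth range), its time snapped to
#' the nearest grid time; then, per grid depth, values are linearly
#' interpolated in time between consecutive observed profiles no more
#' than `max_gap_h` apart. Grid times outside any such bracketing pair
#' are masked, as are times before the first and after the last profile.
#'
#' @param profiles Long QC'd profile tibble (`time`, `depth_m`, and the
#'   variable column).
#' @param variable Name of the column to grid.
#' @param depth_grid Depth axis, m.
#' @param time_step_min Grid time step, minutes.
#' @param max_gap_h Maximum interpolation interval, hours.
#' @param units Unit string carried into the object.
#' @return An `ice_section`: list with `depth_m`, `time`, `values`
#'   (depth x time matrix, NA = masked), `variable`, `units`.
#' @export
build_section <- function(profiles, variable,
                          depth_grid = seq(0, 18.5, by = 0.1),
                          time_step_min = 20, max_gap_h = 6,
                          units = "") {
  if (!variable %in% names(profiles)) {
    abort(paste0("Column `", variable, "` not found in profiles."))
  }
  times <- sort(unique(profiles$time))
  day0 <- as.POSIXct(trunc(min(times), units = "days"), tz = "UTC")
  time_grid <- seq(day0, max(times) + time_step_min * 60,
                   by = time_step_min * 60)
  values <- matrix(NA_real_, length(depth_grid), length(time_grid))

  if (length(times) > 0) {
    # depth-interpolate each profile, snap to nearest grid time
    cols <- vapply(times, function(tm) {
      prof <- profiles[profiles$time == tm, ]
      prof <- prof[order(prof$depth_m), ]
      ok <- !is.na(prof[[variable]])
      if (sum(ok) < 2) return(rep(NA_real_, length(depth_grid)))
      approx(prof$depth_m[ok], prof[[variable]][ok], depth_grid,
             rule = 1)$y
    }, numeric(length(depth_grid)))
    snap <- vapply(times, function(tm) {
      which.min(abs(as.numeric(time_grid) - as.numeric(tm)))
    }, integer(1))
    obs_t <- as.numeric(time_grid[snap])
    grid_t <- as.numeric(time_grid)
    max_gap_s <- max_gap_h * 3600

    for (i in seq_along(depth_grid)) {
      v <- cols[i, ]
      ok <- !is.na(v)
      if (!any(ok)) next
      ot <- obs_t[ok]; ov <- v[ok]
      values[i, snap[ok]] <- ov
      if (length(ot) >= 2) {
        left <- findInterval(grid_t, ot)
        interior <- left >= 1 & left < length(ot) &
          grid_t > ot[pmax(left, 1)]
        idx <- which(interior)
        if (length(idx) > 0) {
          l <- left[idx]
          gap_ok <- (ot[l + 1] - ot[l]) <= max_gap_s
          idx <- idx[gap_ok]; l <- l[gap_ok]
          if (length(idx) > 0) {
            f <- (grid_t[idx] - ot[l]) / (ot[l + 1] - ot[l])
            values[cbind(i, idx)] <- ov[l] + f * (ov[l + 1] - ov[l])
          }
        }
      }
    }
  }
  structure(
    list(depth_m = depth_grid, time = time_grid, values = values,
         variable = variable, units = units),
    class = "ice_section"
  )
}

#' @export
print.ice_section <- function(x, ...) {
  cat("<ice_section>", x$variable,
      if (nzchar(x$units)) paste0("(", x$units, ")"), "\n")
  cat(sprintf("  %d depths x %d times, %.1f%% masked\n",
              length(x$depth_m), length(x$time),
              100 * mean(is.na(x$values))))
  invisible(x)
}

#' Tidy a time-depth section into a long tibble
#'
#' @param x An `ice_section`.
#' @param ... Unused.
#' @return Tibble with `time`, `depth_m`, `value` (NA where masked).
#' @export
tidy.ice_section <- function(x, ...) {
  tibble(
    time = rep(x$time, each = length(x$depth_m)),
    depth_m = rep(x$depth_m, times = length(x$time)),
    value = as.vector(x$values)
  )
}
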