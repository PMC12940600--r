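#' Generate a synthetic hourly monitoring record
#'
#' Simulates one hour-resolution year (or any calendar window the
#' configuration's phase calendar spans) of pollutant concentrations and
#' meteorology with the statistical structure the downstream analysis
#' assumes:
#'
#' * per-phase pollutant levels equal to the configured phase means, with a
#'   mean-zero within-day sinusoid and truncated-Gaussian hourly noise;
#' * sinusoidal seasonal cycles for temperature, humidity and radiation with
#'   austral phase (temperature maximum in January);
#' * a wind-speed anomaly coupling into PM10/PM2.5 with non-positive slope
#'   (dispersion);
#' * Poisson-timed SO2 spike events with exponential magnitudes that decay
#'   across phases (episodic point-source emissions);
#' * a weekday (Mon-Fri) multiplicative uplift on NO2 (traffic signal);
#' * scheduled missingness blocks (instrument outages).
#'
#' Timestamps are naive local time at hourly resolution; days are local
#' calendar dates. With the configured seed fixed the output is
#' bit-identical across runs.
#'
#' @param config A [scenario_config()].
#' @return A tibble with one row per hour and columns
#'   `timestamp, pm10, pm25, no2, o3, so2, temp, ws, wd, rh, pres, rad`.
#' @export
#' @examples
#' cfg <- default_ilo_config(seed = 1L)
#' hourly <- generate_scenario(cfg)
#' nrow(hourly) / 24 # days in 2020
generate_scenario <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  win <- calendar_window(config$calendar)
  if (as.integer(win[2] - win[1]) < 1L) {
    stop("simulation window must span at least one full day", call. = FALSE)
  }
  dates <- seq(win[1], win[2], by = "day")
  n_days <- length(dates)
  hours <- rep(0:23, times = n_days)
  date <- rep(dates, each = 24L)
  n <- length(date)
  timestamp <- as.POSIXct(
    paste0(format(date), " ", sprintf("%02d:00:00", hours)),
    tz = "UTC"
  )
  phase <- assign_phase(date, config$calendar)
  doy <- as.integer(format(date, "%j"))
  met <- config$met

  withr::with_seed(config$seed, {
    season <- function(peak_doy) {
      cos(2 * pi * (doy - peak_doy) / 365.25)
    }
    diurnal <- function(peak_hour) cos(2 * pi * (hours - peak_hour) / 24)

    temp <- met$temp_mean + met$temp_seasonal_amp * season(met$temp_peak_doy) +
      met$temp_diurnal_amp * diurnal(14) + stats::rnorm(n, 0, met$temp_sd)
    # humidity runs opposite to temperature (marine layer in winter)
    rh <- met$rh_mean - met$rh_seasonal_amp * season(met$temp_peak_doy) +
      stats::rnorm(n, 0, met$rh_sd)
    rh <- pmin(pmax(rh, 0), 100)
    rad <- met$rad_mean + met$rad_seasonal_amp * season(met$temp_peak_doy) +
      met$rad_diurnal_amp * diurnal(13) + stats::rnorm(n, 0, met$rad_sd)
    rad <- pmax(rad, 0)
    pres <- met$pres_mean + stats::rnorm(n, 0, met$pres_sd)
    ws <- met$wind_mean + met$wind_diurnal_amp * diurnal(15) +
      stats::rnorm(n, 0, met$wind_sd)
    ws <- pmax(ws, 0)
    wd <- stats::runif(n, 0, 360)

    pollutant_noise <- function(sd) {
      if (sd == 0) {
        return(rep(0, n))
      }
      if (config$ar1 > 0) {
        eps <- stats::rnorm(n, 0, sd * sqrt(1 - config$ar1^2))
        as.numeric(stats::filter(eps, config$ar1, method = "recursive"))
      } else {
        stats::rnorm(n, 0, sd)
      }
    }

    base <- function(p) {
      as.numeric(config$phase_means[[p]][as.integer(phase)]) +
        config$diurnal_amp[[p]] * diurnal(13) +
        pollutant_noise(config$noise_sd[[p]])
    }

    ws_anom <- ws - met$wind_mean
    pm10 <- base("pm10") + config$wind_pm_slope * ws_anom
    pm25 <- base("pm25") + config$wind_pm_slope * ws_anom * 0.5
    no2 <- base("no2")
    weekday <- !format(date, "%u") %in% c("6", "7")
    no2[weekday] <- no2[weekday] * (1 + config$no2_weekday_uplift)
    o3 <- base("o3")
    so2 <- base("so2")

    if (config$so2_spike_rate > 0) {
      spike_mean_day <- as.numeric(
        config$so2_spike_mean[as.integer(assign_phase(dates, config$calendar))]
      )
      n_events <- stats::rpois(n_days, config$so2_spike_rate)
      for (d in which(n_events > 0)) {
        hr <- sample.int(24L, n_events[d], replace = TRUE) - 1L
        mag <- stats::rexp(n_events[d], rate = 1 / spike_mean_day[d])
        idx <- (d - 1L) * 24L + hr + 1L
        so2[idx] <- so2[idx] + mag
      }
    }
  })

  out <- tibble::tibble(
    timestamp = timestamp,
    pm10 = pmax(pm10, 0), pm25 = pmax(pm25, 0), no2 = pmax(no2, 0),
    o3 = pmax(o3, 0), so2 = pmax(so2, 0),
    temp = temp, ws = ws, wd = wd, rh = rh, pres = pres, rad = rad
  )
  if (!is.null(config$missingness)) {
    out <- inject_missingness(out, config$missingness)
  }
  out
}

#' Blank out variables over date intervals
#'
#' Sets the named variables to missing on every hour of the given inclusive
#' date intervals, emulating instrument outages. All other cells are left
#' untouched.
#'
#' @param data An hourly dataset as produced by [generate_scenario()].
#' @param blocks Data frame with columns `variable`, `start`, `end`.
#' @return `data` with the scheduled cells set to `NA`.
#' @export
inject_missingness <- function(data, blocks) {
  blocks <- tibble::as_tibble(blocks)
  if (nrow(blocks) == 0) {
    return(data)
  }
  stopifnot(all(c("variable", "start", "end") %in% names(blocks)))
  measurable <- setdiff(names(data), "timestamp")
  unknown <- setdiff(unique(blocks$variable), measurable)
  if (length(unknown) > 0) {
    stop("unknown variable(s) in missingness blocks: ",
      paste(unknown, collapse = ", "),
      call. = FALSE
    )
  }
  date <- as.Date(format(data$timestamp, "%Y-%m-%d"))
  for (i in seq_len(nrow(blocks))) {
    hit <- date >= as.Date(blocks$start[i]) & date <= as.Date(blocks$end[i])
    data[[blocks$variable[i]]][hit] <- NA_real_
  }
  data
}

#' Write an hourly dataset to CSV
#'
#' Writes the canonical hourly dialect: header
#' `timestamp,pm10,pm25,no2,o3,so2,temp,ws,wd,rh,pres,rad`, ISO-8601
#' timestamps, empty field for missing.
#'
#' @param data Hourly dataset.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_hourly_csv <- function(data, path) {
  out <- data
  out$timestamp <- format(out$timestamp, "%Y-%m-%dT%H:%M:%S")
  readr::write_csv(out, path, na = "")
  invisible(path)
}
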