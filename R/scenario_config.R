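#' Scenario configurations for the synthetic hourly generator
#'
#' A `scenario_config` bundles everything [generate_scenario()] needs to
#' produce an hourly pollutant + meteorology record with a known statistical
#' structure: a phase calendar, per-pollutant phase means, seasonal and
#' diurnal cycles for the meteorology, a negative wind-particle coupling,
#' episodic point-source spikes for SO2, a weekday traffic uplift for NO2,
#' hourly noise levels, scheduled missingness blocks, and a seed.
#'
#' All concentrations are in ug/m3, temperature in degC, wind speed in m/s,
#' relative humidity in %, pressure in hPa, radiation in W/m2.
#'
#' @param calendar A [phase_calendar()] covering the simulation window.
#' @param phase_means Named list, one element per pollutant
#'   (`pm10`, `pm25`, `no2`, `o3`, `so2`), each a numeric vector of strictly
#'   positive phase means named by the calendar's phases.
#' @param met Named list of meteorology parameters (see
#'   [default_ilo_config()] for the full set of keys).
#' @param diurnal_amp Named numeric, within-day sinusoid amplitude per
#'   pollutant; the sinusoid averages to zero over each day so daily means are
#'   untouched.
#' @param wind_pm_slope Response of PM10/PM2.5 to the wind-speed anomaly,
#'   ug/m3 per m/s; must be <= 0 (stronger wind disperses particles).
#' @param so2_spike_rate Poisson arrival rate of smelter-type SO2 spike
#'   events, events/day.
#' @param so2_spike_mean Mean spike magnitude (exponential), ug/m3, named by
#'   phase so episodic emissions can decay across the intervention timeline.
#' @param no2_weekday_uplift Fractional uplift applied to NO2 on Mondays to
#'   Fridays (traffic signal); 0 disables it.
#' @param noise_sd Named numeric, hourly Gaussian noise SD per pollutant
#'   (>= 0); values are truncated at zero after noise is added.
#' @param ar1 AR(1) coefficient for the hourly pollutant noise, in [0, 1);
#'   default 0 (white noise). Innovations are scaled so the marginal SD stays
#'   `noise_sd`.
#' @param missingness Data frame with columns `variable`, `start`, `end`
#'   describing scheduled instrument outages, or `NULL`.
#' @param seed Integer seed; a fixed seed makes the generated dataset
#'   bit-identical across runs.
#'
#' @return A list of class `scenario_config`.
#' @seealso [default_ilo_config()], [generate_scenario()]
#' @export
scenario_config <- function(calendar,
                            phase_means,
                            met,
                            diurnal_amp = c(
                              pm10 = 5, pm25 = 2, no2 = 1, o3 = 5, so2 = 2
                            ),
                            wind_pm_slope = -2,
                            so2_spike_rate = 0.1,
                            so2_spike_mean = NULL,
                            no2_weekday_uplift = 0.1,
                            noise_sd = c(
                              pm10 = 15, pm25 = 4, no2 = 0.9,
                              o3 = 4.5, so2 = 8
                            ),
                            ar1 = 0,
                            missingness = NULL,
                            seed = 123L) {
  stopifnot(inherits(calendar, "phase_calendar"))
  pollutants <- c("pm10", "pm25", "no2", "o3", "so2")
  if (!all(pollutants %in% names(phase_means))) {
    stop("phase_means must name all of: ", paste(pollutants, collapse = ", "),
      call. = FALSE
    )
  }
  for (p in pollutants) {
    m <- phase_means[[p]]
    if (!all(calendar$phase %in% names(m))) {
      stop("phase_means$", p, " must be named by every calendar phase",
        call. = FALSE
      )
    }
    if (any(m <= 0)) {
      stop("phase means must be strictly positive (", p, ")", call. = FALSE)
    }
  }
  if (any(noise_sd < 0)) stop("noise_sd must be >= 0", call. = FALSE)
  if (wind_pm_slope > 0) {
    stop("wind_pm_slope must be <= 0 (dispersion)", call. = FALSE)
  }
  if (ar1 < 0 || ar1 >= 1) stop("ar1 must be in [0, 1)", call. = FALSE)
  if (is.null(so2_spike_mean)) {
    so2_spike_mean <- stats::setNames(
      rep(40, nrow(calendar)), calendar$phase
    )
  }
  if (!is.null(missingness)) {
    missingness <- tibble::as_tibble(missingness)
    stopifnot(all(c("variable", "start", "end") %in% names(missingness)))
    missingness$start <- as.Date(missingness$start)
    missingness$end <- as.Date(missingness$end)
  }
  structure(
    list(
      calendar = calendar,
      phase_means = lapply(phase_means[pollutants], function(m) {
        m[calendar$phase]
      }),
      met = met,
      diurnal_amp = diurnal_amp,
      wind_pm_slope = wind_pm_slope,
      so2_spike_rate = so2_spike_rate,
      so2_spike_mean = so2_spike_mean[calendar$phase],
      no2_weekday_uplift = no2_weekday_uplift,
      noise_sd = noise_sd,
      ar1 = ar1,
      missingness = missingness,
      seed = as.integer(seed)
    ),
    class = "scenario_config"
  )
}

#' Default Ilo 2020 scenario
#'
#' The generator's reference conditions: six intervention phases over calendar
#' year 2020 with per-phase pollutant means set to the published Ilo
#' monitoring summaries (e.g. PM2.5 12.60 ug/m3 Pre-Pandemic rising to
#' 16.91 ug/m3 in Phase 1), an austral seasonal cycle (temperature maximum in
#' January, humidity maximum in winter), a weak diurnal cycle per pollutant,
#' a negative wind-particle coupling, episodic SO2 spikes whose magnitude
#' decays across phases, a weekday NO2 uplift, and end-of-year instrument
#' outages for SO2 (from 6 October) and O3 (from 16 October) that leave 9 and
#' 19 valid days respectively in the final phase.
#'
#' @param seed Integer seed for [generate_scenario()].
#' @return A [scenario_config()].
#' @export
default_ilo_config <- function(seed = 123L) {
  cal <- default_ilo_calendar()
  ph <- cal$phase
  pm <- function(x) stats::setNames(x, ph)
  scenario_config(
    calendar = cal,
    phase_means = list(
      pm10 = pm(c(50.93, 53.04, 43.90, 50.00, 35.07, 42.74)),
      pm25 = pm(c(12.60, 14.51, 16.91, 15.04, 10.91, 11.96)),
      no2  = pm(c(5.81, 4.77, 4.81, 4.88, 4.73, 5.06)),
      o3   = pm(c(14.59, 16.18, 21.15, 26.09, 30.31, 25.47)),
      so2  = pm(c(25.57, 24.17, 18.90, 14.00, 10.18, 8.85))
    ),
    met = list(
      temp_mean = 21, temp_seasonal_amp = 4, temp_peak_doy = 15,
      temp_diurnal_amp = 3, temp_sd = 1,
      rh_mean = 70, rh_seasonal_amp = 5, rh_sd = 4,
      rad_mean = 250, rad_seasonal_amp = 120, rad_diurnal_amp = 280,
      rad_sd = 30,
      pres_mean = 1012, pres_sd = 2,
      wind_mean = 4, wind_sd = 1.2, wind_diurnal_amp = 1
    ),
    wind_pm_slope = -2,
    so2_spike_rate = 0.1,
    so2_spike_mean = pm(c(40, 30, 20, 12, 8, 5)),
    no2_weekday_uplift = 0.1,
    missingness = tibble::tibble(
      variable = c("so2", "o3"),
      start = as.Date(c("2020-10-06", "2020-10-16")),
      end = as.Date(c("2020-12-31", "2020-12-31"))
    ),
    seed = seed
  )
}

#' A noise-free variant of a scenario
#'
#' Sets every stochastic ingredient of `config` to zero (hourly noise, spikes,
#' wind variability and coupling, weekday uplift, meteorology noise) so that
#' every generated daily mean equals its configured phase mean exactly.
#' Used for arithmetic-identity checks and for reproducing published
#' summary-table inputs through the full pipeline.
#'
#' @param config A [scenario_config()].
#' @param keep_missingness Keep the configured outage blocks? Default `TRUE`.
#' @return A modified [scenario_config()].
#' @export
zero_noise_config <- function(config, keep_missingness = TRUE) {
  stopifnot(inherits(config, "scenario_config"))
  config$noise_sd[] <- 0
  config$diurnal_amp[] <- 0
  config$so2_spike_rate <- 0
  config$no2_weekday_uplift <- 0
  config$wind_pm_slope <- 0
  config$met$temp_sd <- 0
  config$met$rh_sd <- 0
  config$met$rad_sd <- 0
  config$met$pres_sd <- 0
  config$met$wind_sd <- 0
  if (!keep_missingness) config$missingness <- NULL
  config
}

#' Read and write scenario configurations
#'
#' YAML serialization of a [scenario_config()] (dates as ISO strings). The
#' round trip `read_scenario_config(write_scenario_config(cfg, f))` returns a
#' configuration equal to `cfg`.
#'
#' @param config A [scenario_config()].
#' @param path File path.
#' @return `write_scenario_config()` returns `path` invisibly;
#'   `read_scenario_config()` returns a [scenario_config()].
#' @export
write_scenario_config <- function(config, path) {
  stopifnot(inherits(config, "scenario_config"))
  cal <- config$calendar
  x <- list(
    calendar = list(
      phase = as.list(cal$phase),
      start = as.list(format(cal$start)),
      end = as.list(format(cal$end)),
      reference = reference_phase(cal)
    ),
    phase_means = lapply(config$phase_means, as.list),
    met = config$met,
    diurnal_amp = as.list(config$diurnal_amp),
    wind_pm_slope = config$wind_pm_slope,
    so2_spike_rate = config$so2_spike_rate,
    so2_spike_mean = as.list(config$so2_spike_mean),
    no2_weekday_uplift = config$no2_weekday_uplift,
    noise_sd = as.list(config$noise_sd),
    ar1 = config$ar1,
    seed = config$seed
  )
  if (!is.null(config$missingness)) {
    x$missingness <- list(
      variable = as.list(config$missingness$variable),
      start = as.list(format(config$missingness$start)),
      end = as.list(format(config$missingness$end))
    )
  }
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_scenario_config
#' @export
read_scenario_config <- function(path) {
  x <- yaml::read_yaml(path)
  cal <- phase_calendar(
    phase = unlist(x$calendar$phase),
    start = as.Date(unlist(x$calendar$start)),
    end = as.Date(unlist(x$calendar$end)),
    reference = x$calendar$reference
  )
  miss <- NULL
  if (!is.null(x$missingness)) {
    miss <- tibble::tibble(
      variable = unlist(x$missingness$variable),
      start = as.Date(unlist(x$missingness$start)),
      end = as.Date(unlist(x$missingness$end))
    )
  }
  scenario_config(
    calendar = cal,
    phase_means = lapply(x$phase_means, unlist),
    met = x$met,
    diurnal_amp = unlist(x$diurnal_amp),
    wind_pm_slope = x$wind_pm_slope,
    so2_spike_rate = x$so2_spike_rate,
    so2_spike_mean = unlist(x$so2_spike_mean),
    no2_weekday_uplift = x$no2_weekday_uplift,
    noise_sd = unlist(x$noise_sd),
    ar1 = x$ar1,
    missingness = miss,
    seed = x$seed
  )
}
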