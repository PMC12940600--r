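# Shared fixtures, built in code.

# A two-phase, three-week calendar for fast generator tests.
mini_calendar <- function() {
  phase_calendar(
    phase = c("Before", "After"),
    start = as.Date(c("2020-01-01", "2020-01-11")),
    end = as.Date(c("2020-01-10", "2020-01-21")),
    reference = "Before"
  )
}

mini_config <- function(seed = 42L, ...) {
  cal <- mini_calendar()
  pm <- function(b, a) stats::setNames(c(b, a), cal$phase)
  scenario_config(
    calendar = cal,
    phase_means = list(
      pm10 = pm(50, 40), pm25 = pm(12, 16), no2 = pm(5, 4.5),
      o3 = pm(15, 25), so2 = pm(25, 10)
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
    so2_spike_mean = pm(40, 10),
    seed = seed,
    ...
  )
}

# A daily dataset with phase labels and exact per-phase means, for
# arithmetic-identity checks (no generator involved).
daily_with_means <- function(means, n_per_phase = 10) {
  phases <- names(means)
  rows <- lapply(seq_along(phases), function(i) {
    # values symmetric around the mean so the mean is exact
    dev <- seq(-1, 1, length.out = n_per_phase)
    tibble::tibble(
      date = as.Date("2020-01-01") + (i - 1) * n_per_phase +
        seq_len(n_per_phase) - 1,
      phase = phases[i],
      pm25 = means[[i]] + dev
    )
  })
  out <- dplyr::bind_rows(rows)
  out$phase <- factor(out$phase, levels = phases)
  out$weekday <- !format(out$date, "%u") %in% c("6", "7")
  out
}

expect_tibble_equal <- function(a, b) {
  testthat::expect_identical(as.data.frame(a), as.data.frame(b))
}
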