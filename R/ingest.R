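#' Read an hourly monitoring CSV
#'
#' Reads the canonical hourly dialect written by [write_hourly_csv()]
#' (`timestamp,pm10,pm25,no2,o3,so2,temp,ws,wd,rh,pres,rad`, ISO-8601
#' timestamps, empty field = missing). Cells that fail to parse and negative
#' concentration or wind-speed values are flagged missing; their count is
#' attached as attribute `n_invalid` and reported in a warning. Duplicated or
#' non-increasing timestamps are an error.
#'
#' @param path CSV file path.
#' @return A tibble of hourly records; attribute `n_invalid` counts cells
#'   invalidated during reading.
#' @export
read_hourly_csv <- function(path) {
  mandatory <- c(
    "timestamp", "pm10", "pm25", "no2", "o3", "so2", "temp", "ws", "rh"
  )
  header <- names(readr::read_csv(
    path,
    n_max = 0, show_col_types = FALSE, progress = FALSE
  ))
  absent <- setdiff(mandatory, header)
  if (length(absent) > 0) {
    stop("missing mandatory column(s): ", paste(absent, collapse = ", "),
      call. = FALSE
    )
  }
  data <- suppressWarnings(readr::read_csv(
    path,
    col_types = readr::cols(
      timestamp = readr::col_character(),
      .default = readr::col_double()
    ),
    na = c("", "NA"), progress = FALSE
  ))
  n_invalid <- nrow(readr::problems(data))
  data$timestamp <- as.POSIXct(
    data$timestamp,
    format = "%Y-%m-%dT%H:%M:%S", tz = "UTC"
  )
  if (anyNA(data$timestamp)) {
    stop("unparseable timestamp(s) in ", path, call. = FALSE)
  }
  if (anyDuplicated(data$timestamp)) {
    stop("duplicated timestamp(s) in ", path, call. = FALSE)
  }
  if (is.unsorted(data$timestamp, strictly = TRUE)) {
    stop("timestamps must be strictly increasing", call. = FALSE)
  }
  # concentrations and wind speed cannot be negative
  for (v in intersect(c("pm10", "pm25", "no2", "o3", "so2", "ws"), header)) {
    bad <- !is.na(data[[v]]) & data[[v]] < 0
    n_invalid <- n_invalid + sum(bad)
    data[[v]][bad] <- NA_real_
  }
  if (n_invalid > 0) {
    warning(n_invalid, " invalid cell(s) set to missing while reading ", path,
      call. = FALSE
    )
  }
  attr(data, "n_invalid") <- n_invalid
  data
}

#' Aggregate hourly records to QC-gated daily means
#'
#' Computes, per local calendar date and variable, the mean of the valid
#' (non-missing) hours, retained only when at least `min_valid_hours` hours
#' are valid (the 75%-completeness rule at the default 18); days below the
#' threshold are missing for that variable only. Valid-hour counts are kept
#' alongside as `<var>_n` columns. Also attaches the daily maximum rolling
#' 8-hour ozone mean ([compute_o3_8h_max()]), a weekday flag, and -- when a
#' calendar is supplied -- the phase label.
#'
#' @param data Hourly dataset ([generate_scenario()] / [read_hourly_csv()]).
#' @param min_valid_hours Minimum valid hours for a daily mean; integer in
#'   1..24, default 18.
#' @param calendar Optional [phase_calendar()]; when given, a `phase` factor
#'   is added (every date must fall inside the calendar).
#' @return A tibble with one row per date: `date`, optionally `phase`, per
#'   variable the daily mean and `<var>_n` valid-hour count, `o3_8h_max`, and
#'   logical `weekday`.
#' @export
aggregate_daily <- function(data, min_valid_hours = 18L, calendar = NULL) {
  min_valid_hours <- as.integer(min_valid_hours)
  stopifnot(min_valid_hours >= 1L, min_valid_hours <= 24L)
  vars <- setdiff(names(data), "timestamp")
  date <- as.Date(format(data$timestamp, "%Y-%m-%d"))

  daily <- tibble::tibble(date = sort(unique(date)))
  for (v in vars) {
    x <- data[[v]]
    n_valid <- tapply(!is.na(x), date, sum)
    m <- tapply(x, date, mean, na.rm = TRUE)
    m[is.nan(m)] <- NA_real_
    m[n_valid < min_valid_hours] <- NA_real_
    daily[[v]] <- as.numeric(m[format(daily$date)])
    daily[[paste0(v, "_n")]] <- as.integer(n_valid[format(daily$date)])
  }
  if ("o3" %in% vars) {
    o3_8h <- compute_o3_8h_max(data)
    daily <- dplyr::left_join(daily, o3_8h, by = "date")
  }
  daily$weekday <- !format(daily$date, "%u") %in% c("6", "7")
  if (!is.null(calendar)) {
    daily <- tibble::add_column(
      daily,
      phase = assign_phase(daily$date, calendar), .after = "date"
    )
  }
  daily
}

#' Daily maximum 8-hour ozone mean
#'
#' Computes, for each date, the maximum over rolling 8-hour windows (indexed
#' by window start hour) of the mean hourly ozone. A window is valid when at
#' least 6 of its 8 hours are valid; a date with no valid window is missing.
#' The hourly series is re-indexed onto a continuous hour grid first, so gaps
#' count as invalid hours.
#'
#' @param data Hourly dataset with an `o3` column.
#' @return A tibble `date`, `o3_8h_max` (ug/m3).
#' @export
compute_o3_8h_max <- function(data) {
  stopifnot("o3" %in% names(data))
  grid <- seq(min(data$timestamp), max(data$timestamp), by = "hour")
  x <- rep(NA_real_, length(grid))
  x[match(data$timestamp, grid)] <- data$o3
  win_mean <- zoo::rollapply(
    x,
    width = 8,
    FUN = function(w) {
      if (sum(!is.na(w)) >= 6) mean(w, na.rm = TRUE) else NA_real_
    },
    align = "left", fill = NA_real_
  )
  start_date <- as.Date(format(grid, "%Y-%m-%d"))
  mx <- tapply(win_mean, start_date, function(z) {
    if (all(is.na(z))) NA_real_ else max(z, na.rm = TRUE)
  })
  tibble::tibble(
    date = as.Date(names(mx)),
    o3_8h_max = as.numeric(mx)
  )
}

#' Standardize predictor columns
#'
#' Mean-centers and scales (sample, n-1 denominator) the named columns over
#' their non-missing rows, returning the transformed data together with the
#' scaling constants needed to back-transform coefficients.
#'
#' @param daily Daily dataset.
#' @param variables Character vector of column names to standardize.
#' @return A list: `data` (transformed tibble) and `scaling` (tibble
#'   `variable`, `mean`, `sd`).
#' @export
standardize_predictors <- function(daily, variables) {
  stopifnot(all(variables %in% names(daily)))
  scaling <- tibble::tibble(
    variable = variables,
    mean = NA_real_, sd = NA_real_
  )
  for (i in seq_along(variables)) {
    v <- variables[i]
    x <- daily[[v]]
    if (sum(!is.na(x)) < 2) {
      stop("variable '", v, "' has fewer than 2 non-missing values",
        call. = FALSE
      )
    }
    m <- mean(x, na.rm = TRUE)
    s <- stats::sd(x, na.rm = TRUE)
    if (s == 0) {
      stop("variable '", v, "' has zero variance", call. = FALSE)
    }
    daily[[v]] <- (x - m) / s
    scaling$mean[i] <- m
    scaling$sd[i] <- s
  }
  list(data = daily, scaling = scaling)
}
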