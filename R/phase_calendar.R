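#' Phase calendars
#'
#' A phase calendar is an ordered set of named, non-overlapping, inclusive
#' date intervals, one of which is designated the reference phase for all
#' contrasts. It encodes the intervention timeline against which pollutant
#' changes are assessed.
#'
#' @param phase Character vector of phase names (unique).
#' @param start,end Dates (inclusive on both ends).
#' @param reference Name of the reference phase; must appear in `phase`.
#'
#' @return A tibble of class `phase_calendar` with columns `phase`, `start`,
#'   `end` and attribute `reference`.
#' @export
#' @examples
#' cal <- phase_calendar(
#'   phase = c("Before", "After"),
#'   start = as.Date(c("2020-01-01", "2020-07-01")),
#'   end   = as.Date(c("2020-06-30", "2020-12-31")),
#'   reference = "Before"
#' )
#' assign_phase(as.Date("2020-08-15"), cal)
phase_calendar <- function(phase, start, end, reference = phase[[1]]) {
  start <- as.Date(start)
  end <- as.Date(end)
  stopifnot(length(phase) == length(start), length(start) == length(end))
  if (anyDuplicated(phase)) {
    stop("phase names must be unique", call. = FALSE)
  }
  if (any(end < start)) {
    stop("each phase must end on or after its start date", call. = FALSE)
  }
  ord <- order(start)
  phase <- phase[ord]
  start <- start[ord]
  end <- end[ord]
  if (length(start) > 1L && any(start[-1L] <= end[-length(end)])) {
    stop("phase intervals must not overlap", call. = FALSE)
  }
  if (!reference %in% phase) {
    stop("reference phase '", reference, "' is not in the calendar",
      call. = FALSE
    )
  }
  out <- tibble::tibble(phase = phase, start = start, end = end)
  class(out) <- c("phase_calendar", class(out))
  attr(out, "reference") <- reference
  out
}

#' @rdname phase_calendar
#' @param x A `phase_calendar`.
#' @export
reference_phase <- function(x) {
  stopifnot(inherits(x, "phase_calendar"))
  attr(x, "reference")
}

#' Default 2020 Ilo intervention calendar
#'
#' The six 2020 pandemic-response phases decreed for Peru, used throughout the
#' worked examples: Pre-Pandemic (1 Jan - 15 Mar), Strict Lockdown
#' (16 Mar - 3 May), then four progressive reopening phases covering the rest
#' of the calendar year. Pre-Pandemic is the reference.
#'
#' @return A [phase_calendar()].
#' @export
default_ilo_calendar <- function() {
  phase_calendar(
    phase = c(
      "Pre-Pandemic", "Strict Lockdown",
      "Phase 1", "Phase 2", "Phase 3", "Phase 4"
    ),
    start = as.Date(c(
      "2020-01-01", "2020-03-16", "2020-05-04",
      "2020-06-05", "2020-07-01", "2020-09-27"
    )),
    end = as.Date(c(
      "2020-03-15", "2020-05-03", "2020-06-04",
      "2020-06-30", "2020-09-26", "2020-12-31"
    )),
    reference = "Pre-Pandemic"
  )
}

#' Assign calendar phases to dates
#'
#' Maps each date to the unique calendar interval containing it. Dates outside
#' every interval are an error: the calendar is required to cover the analysis
#' window, so an uncovered date indicates a configuration mistake rather than
#' a value to silently drop.
#'
#' @param date A `Date` vector.
#' @param calendar A [phase_calendar()].
#'
#' @return A factor with the calendar's phase names as levels, in calendar
#'   order.
#' @export
assign_phase <- function(date, calendar) {
  stopifnot(inherits(calendar, "phase_calendar"))
  date <- as.Date(date)
  idx <- rep.int(NA_integer_, length(date))
  for (i in seq_len(nrow(calendar))) {
    hit <- !is.na(date) & date >= calendar$start[i] & date <= calendar$end[i]
    idx[hit] <- i
  }
  if (anyNA(idx[!is.na(date)])) {
    bad <- date[!is.na(date) & is.na(idx)]
    stop(
      "date(s) outside the phase calendar: ",
      paste(utils::head(format(bad), 5L), collapse = ", "),
      call. = FALSE
    )
  }
  factor(calendar$phase[idx], levels = calendar$phase)
}

#' Span of a phase calendar
#'
#' @param calendar A [phase_calendar()].
#' @return A length-2 Date vector: first start and last end.
#' @export
calendar_window <- function(calendar) {
  stopifnot(inherits(calendar, "phase_calendar"))
  c(min(calendar$start), max(calendar$end))
}
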