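#' WHO 2021 24-hour air-quality guideline levels
#'
#' Named vector of guideline concentrations (ug/m3): PM10 45, PM2.5 15,
#' NO2 25, SO2 40 as 24-h means, and O3 100 as the daily maximum 8-hour mean.
#'
#' @export
who_2021_guidelines <- c(pm10 = 45, pm25 = 15, no2 = 25, o3 = 100, so2 = 40)

default_pollutants <- c("pm10", "pm25", "no2", "o3", "so2")

#' Phase-stratified descriptive statistics
#'
#' Mean, standard deviation (sample), median, range and day count per
#' pollutant and phase, computed over non-missing days. A phase with no valid
#' days yields an `n = 0` row with missing statistics; with a single day the
#' SD is missing.
#'
#' @param daily Daily dataset with a `phase` column ([aggregate_daily()]).
#' @param pollutants Columns to summarize; defaults to the five pollutants.
#' @return A tibble `pollutant, phase, mean, sd, median, min, max, n`.
#' @export
phase_summary <- function(daily, pollutants = default_pollutants) {
  stopifnot("phase" %in% names(daily))
  pollutants <- intersect(pollutants, names(daily))
  tidyr::expand_grid(
    pollutant = pollutants,
    phase = levels(daily$phase)
  ) |>
    dplyr::rowwise() |>
    dplyr::mutate(
      stats = {
        x <- daily[[.data$pollutant]][daily$phase == .data$phase]
        x <- x[!is.na(x)]
        list(tibble::tibble(
          mean = if (length(x) > 0) mean(x) else NA_real_,
          sd = if (length(x) > 1) stats::sd(x) else NA_real_,
          median = if (length(x) > 0) stats::median(x) else NA_real_,
          min = if (length(x) > 0) min(x) else NA_real_,
          max = if (length(x) > 0) max(x) else NA_real_,
          n = length(x)
        ))
      }
    ) |>
    dplyr::ungroup() |>
    tidyr::unnest("stats") |>
    dplyr::mutate(phase = factor(.data$phase, levels = levels(daily$phase)))
}

#' Percent change versus the reference phase
#'
#' For each pollutant and phase, the percentage change of the phase mean
#' relative to the reference-phase mean,
#' `100 * (mean_i - mean_ref) / mean_ref`, with a 95% interval built on the
#' difference scale -- `diff +/- 1.96 * sqrt(SE_i^2 + SE_ref^2)` with
#' standard errors of the mean -- then divided by the reference mean. The
#' reference phase reports exactly 0 with a symmetric interval.
#'
#' @param daily Daily dataset with `phase`.
#' @param reference_phase Name of the reference phase; defaults to the first
#'   phase level.
#' @param pollutants Pollutant columns.
#' @return A tibble `pollutant, phase, abs_change, pct_change, ci_lo, ci_hi`
#'   (changes in ug/m3 and %).
#' @export
percent_change <- function(daily, reference_phase = levels(daily$phase)[1],
                           pollutants = default_pollutants) {
  stopifnot("phase" %in% names(daily))
  pollutants <- intersect(pollutants, names(daily))
  out <- list()
  for (p in pollutants) {
    ref <- daily[[p]][daily$phase == reference_phase]
    ref <- ref[!is.na(ref)]
    if (length(ref) < 2) {
      stop("reference phase '", reference_phase, "' needs n >= 2 for ", p,
        call. = FALSE
      )
    }
    m_ref <- mean(ref)
    if (m_ref == 0) {
      stop("reference mean is zero for ", p, call. = FALSE)
    }
    se_ref <- stats::sd(ref) / sqrt(length(ref))
    rows <- lapply(levels(daily$phase), function(ph) {
      x <- daily[[p]][daily$phase == ph]
      x <- x[!is.na(x)]
      if (length(x) == 0) {
        return(tibble::tibble(
          pollutant = p, phase = ph, abs_change = NA_real_,
          pct_change = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_
        ))
      }
      diff <- mean(x) - m_ref
      se_i <- if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else 0
      se_d <- if (ph == reference_phase) 0 else sqrt(se_i^2 + se_ref^2)
      tibble::tibble(
        pollutant = p, phase = ph,
        abs_change = if (ph == reference_phase) 0 else diff,
        pct_change = if (ph == reference_phase) 0 else 100 * diff / m_ref,
        ci_lo = 100 * ((if (ph == reference_phase) 0 else diff) -
          1.96 * se_d) / m_ref,
        ci_hi = 100 * ((if (ph == reference_phase) 0 else diff) +
          1.96 * se_d) / m_ref
      )
    })
    out[[p]] <- dplyr::bind_rows(rows)
  }
  dplyr::bind_rows(out) |>
    dplyr::mutate(phase = factor(.data$phase, levels = levels(daily$phase)))
}

#' Kruskal-Wallis omnibus test with Dunn's post hoc contrasts
#'
#' Omnibus tie-corrected Kruskal-Wallis H across phases (via
#' [stats::kruskal.test()]) followed by Dunn's pairwise z tests on the pooled
#' ranks with the tie-corrected variance
#' `(N(N+1)/12 - T/(12(N-1))) * (1/n_i + 1/n_j)` where
#' `T = sum(t^3 - t)` over tie groups, and Benjamini-Hochberg adjustment
#' across all phase pairs.
#'
#' @param daily Daily dataset with `phase`.
#' @param pollutant Column name to test.
#' @return A list: `h`, `df`, `p_omnibus`, and `pairs` (tibble
#'   `phase_a, phase_b, z, p, p_adj`).
#' @export
kruskal_dunn <- function(daily, pollutant) {
  stopifnot(pollutant %in% names(daily), "phase" %in% names(daily))
  keep <- !is.na(daily[[pollutant]])
  x <- daily[[pollutant]][keep]
  g <- droplevels(daily$phase[keep])
  if (nlevels(g) < 2 || any(table(g) < 2)) {
    stop("need >= 2 phases with >= 2 observations each", call. = FALSE)
  }
  if (length(unique(x)) == 1) {
    kw <- list(statistic = c(H = 0), parameter = nlevels(g) - 1, p.value = 1)
  } else {
    kw <- stats::kruskal.test(x, g)
  }
  r <- rank(x)
  n <- length(x)
  ties <- table(x)
  tie_term <- sum(ties^3 - ties) / (12 * (n - 1))
  var_unit <- n * (n + 1) / 12 - tie_term
  lv <- levels(g)
  combos <- utils::combn(lv, 2)
  pairs <- tibble::tibble(
    phase_a = combos[1, ], phase_b = combos[2, ],
    z = NA_real_, p = NA_real_
  )
  for (k in seq_len(ncol(combos))) {
    i <- combos[1, k]
    j <- combos[2, k]
    ni <- sum(g == i)
    nj <- sum(g == j)
    se <- sqrt(var_unit * (1 / ni + 1 / nj))
    z <- if (se == 0) 0 else {
      (mean(r[g == i]) - mean(r[g == j])) / se
    }
    pairs$z[k] <- z
    pairs$p[k] <- 2 * stats::pnorm(-abs(z))
  }
  pairs$p_adj <- stats::p.adjust(pairs$p, method = "BH")
  list(
    h = unname(kw$statistic),
    df = unname(kw$parameter),
    p_omnibus = kw$p.value,
    pairs = pairs
  )
}

#' Spearman rank correlation matrix
#'
#' Pairwise-complete Spearman rho between the given columns. Cells with fewer
#' than 3 complete pairs are missing.
#'
#' @param daily Daily dataset.
#' @param variables Columns to correlate.
#' @return A symmetric numeric matrix with unit diagonal.
#' @export
spearman_matrix <- function(daily, variables) {
  stopifnot(all(variables %in% names(daily)))
  k <- length(variables)
  m <- matrix(NA_real_, k, k, dimnames = list(variables, variables))
  diag(m) <- 1
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      xi <- daily[[variables[i]]]
      xj <- daily[[variables[j]]]
      ok <- !is.na(xi) & !is.na(xj)
      if (sum(ok) >= 3) {
        rho <- stats::cor(xi[ok], xj[ok], method = "spearman")
        m[i, j] <- rho
        m[j, i] <- rho
      }
    }
  }
  m
}

#' Guideline exceedance frequencies
#'
#' Counts, per pollutant and phase, the days whose daily value strictly
#' exceeds the guideline (ozone compared on the daily maximum 8-hour mean,
#' all others on the 24-h mean). Fractions use valid days as denominator; a
#' phase with zero valid days reports a missing fraction.
#'
#' @param daily Daily dataset with `phase` (and `o3_8h_max` if `o3` is among
#'   the guidelines).
#' @param guidelines Named vector of positive guideline levels (ug/m3);
#'   defaults to [who_2021_guidelines].
#' @return A tibble `pollutant, phase, n_exceed, n_valid, fraction`.
#' @export
exceedance_frequency <- function(daily, guidelines = who_2021_guidelines) {
  stopifnot(all(guidelines > 0), "phase" %in% names(daily))
  rows <- list()
  for (p in names(guidelines)) {
    col <- if (p == "o3") "o3_8h_max" else p
    if (!col %in% names(daily)) next
    for (ph in levels(daily$phase)) {
      x <- daily[[col]][daily$phase == ph]
      x <- x[!is.na(x)]
      rows[[length(rows) + 1]] <- tibble::tibble(
        pollutant = p, phase = ph,
        n_exceed = sum(x > guidelines[[p]]),
        n_valid = length(x),
        fraction = if (length(x) > 0) {
          sum(x > guidelines[[p]]) / length(x)
        } else {
          NA_real_
        }
      )
    }
  }
  dplyr::bind_rows(rows) |>
    dplyr::mutate(phase = factor(.data$phase, levels = levels(daily$phase)))
}

#' Weekday versus weekend contrast per phase
#'
#' Difference of means (weekday minus weekend) of a pollutant within each
#' phase, with a Welch (unequal-variance) 95% interval. Strata with fewer
#' than 2 days on either side are flagged (`ok = FALSE`, missing interval).
#'
#' @param daily Daily dataset with `phase` and logical `weekday`.
#' @param pollutant Column to contrast.
#' @return A tibble
#'   `phase, diff, ci_lo, ci_hi, n_weekday, n_weekend, ok`.
#' @export
weekday_weekend_contrast <- function(daily, pollutant) {
  stopifnot(
    pollutant %in% names(daily),
    all(c("phase", "weekday") %in% names(daily))
  )
  rows <- lapply(levels(daily$phase), function(ph) {
    sel <- daily$phase == ph & !is.na(daily[[pollutant]])
    wd <- daily[[pollutant]][sel & daily$weekday]
    we <- daily[[pollutant]][sel & !daily$weekday]
    if (length(wd) < 2 || length(we) < 2) {
      return(tibble::tibble(
        phase = ph, diff = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
        n_weekday = length(wd), n_weekend = length(we), ok = FALSE
      ))
    }
    d <- mean(wd) - mean(we)
    se <- sqrt(stats::var(wd) / length(wd) + stats::var(we) / length(we))
    if (se > 0) {
      # Welch-Satterthwaite degrees of freedom
      df <- se^4 / (
        (stats::var(wd) / length(wd))^2 / (length(wd) - 1) +
          (stats::var(we) / length(we))^2 / (length(we) - 1)
      )
      half <- stats::qt(0.975, df) * se
    } else {
      half <- 0 # both strata constant: degenerate interval at the point
    }
    tibble::tibble(
      phase = ph, diff = d,
      ci_lo = d - half, ci_hi = d + half,
      n_weekday = length(wd), n_weekend = length(we), ok = TRUE
    )
  })
  dplyr::bind_rows(rows) |>
    dplyr::mutate(phase = factor(.data$phase, levels = levels(daily$phase)))
}
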