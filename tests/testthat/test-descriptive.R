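test_that("phase summaries report the standard five statistics", {
  d <- tibble::tibble(
    date = as.Date("2020-01-01") + 0:3,
    phase = factor(c("A", "A", "A", "B"), levels = c("A", "B", "C")),
    pm25 = c(1, 2, 3, 7)
  )
  s <- phase_summary(d, "pm25")
  a <- s[s$phase == "A", ]
  expect_equal(a$mean, 2)
  expect_equal(a$sd, 1)
  expect_equal(a$median, 2)
  expect_equal(c(a$min, a$max), c(1, 3))
  expect_equal(a$n, 3)
  # single observation: sd undefined
  b <- s[s$phase == "B", ]
  expect_equal(b$n, 1)
  expect_true(is.na(b$sd))
  # empty phase: n = 0 with missing statistics
  cc <- s[s$phase == "C", ]
  expect_equal(cc$n, 0)
  expect_true(is.na(cc$mean))
})

test_that("percent change reproduces the published contrast arithmetic", {
  d <- daily_with_means(c(
    "Pre-Pandemic" = 12.60, "Phase 1" = 16.91, "Phase 3" = 10.91
  ))
  names(d)[names(d) == "pm25"] <- "pm25"
  pc <- percent_change(d, "Pre-Pandemic", "pm25")
  expect_equal(
    round(pc$pct_change[pc$phase == "Phase 1"], 1), 34.2
  )
  expect_equal(
    round(pc$pct_change[pc$phase == "Phase 3"], 1), -13.4
  )
  # reference contrast is exactly zero with a symmetric interval
  ref <- pc[pc$phase == "Pre-Pandemic", ]
  expect_identical(ref$pct_change, 0)
  expect_equal(ref$ci_lo, -ref$ci_hi)
  # intervals bracket the point estimate
  expect_true(all(pc$ci_lo <= pc$pct_change & pc$pct_change <= pc$ci_hi))
})

test_that("identical group means give a zero change whose CI covers zero", {
  d <- daily_with_means(c(A = 10, B = 10))
  pc <- percent_change(d, "A", "pm25")
  b <- pc[pc$phase == "B", ]
  expect_equal(b$pct_change, 0, tolerance = 1e-12)
  expect_lte(b$ci_lo, 0)
  expect_gte(b$ci_hi, 0)
  # degenerate reference mean rejected
  dz <- daily_with_means(c(A = 0.0001, B = 5))
  dz$pm25[dz$phase == "A"] <- c(-1, 1, rep(0, 8))
  expect_error(percent_change(dz, "A", "pm25"), "zero")
})

test_that("Kruskal-Wallis H matches the explicit rank formula", {
  d <- tibble::tibble(
    date = as.Date("2020-01-01") + 0:5,
    phase = factor(rep(c("A", "B", "C"), each = 2)),
    pm25 = c(1, 2, 3, 4, 5, 6)
  )
  res <- kruskal_dunn(d, "pm25")
  # hand computation: ranks 1..6, group mean ranks 1.5/3.5/5.5, grand 3.5
  # H = 12/(6*7) * sum(2 * (rbar - 3.5)^2) = (12/42) * 16 = 32/7
  expect_equal(res$h, 32 / 7, tolerance = 1e-12)
  # independent oracle
  expect_equal(res$h, unname(stats::kruskal.test(d$pm25, d$phase)$statistic))
  expect_equal(nrow(res$pairs), 3)
  expect_equal(res$pairs$p_adj, stats::p.adjust(res$pairs$p, "BH"))
  # step-up arithmetic, verified by hand: (0.01,0.02,0.03) -> all 0.03
  expect_equal(stats::p.adjust(c(0.01, 0.02, 0.03), "BH"), rep(0.03, 3))
})

test_that("degenerate and tied inputs are handled in the rank tests", {
  d <- tibble::tibble(
    date = as.Date("2020-01-01") + 0:5,
    phase = factor(rep(c("A", "B", "C"), each = 2)),
    pm25 = rep(4, 6)
  )
  res <- kruskal_dunn(d, "pm25")
  expect_equal(res$h, 0)
  expect_equal(res$p_omnibus, 1)
  expect_true(all(res$pairs$z == 0))
  # tie-corrected H still matches kruskal.test under heavy ties
  d2 <- tibble::tibble(
    date = as.Date("2020-01-01") + 0:8,
    phase = factor(rep(c("A", "B", "C"), each = 3)),
    pm25 = c(1, 1, 2, 2, 3, 3, 4, 4, 1)
  )
  expect_equal(
    kruskal_dunn(d2, "pm25")$h,
    unname(stats::kruskal.test(d2$pm25, d2$phase)$statistic)
  )
  expect_error(
    kruskal_dunn(d[d$phase == "A", ], "pm25"), ">= 2 phases"
  )
})

test_that("Spearman matrix honours rank invariances", {
  d <- tibble::tibble(
    x = 1:10, cube = (1:10)^3, neg = -(1:10)
  )
  m <- spearman_matrix(d, c("x", "cube", "neg"))
  expect_equal(m["x", "cube"], 1)
  expect_equal(m["x", "neg"], -1)
  expect_equal(m, t(m))
  expect_equal(diag(m), c(x = 1, cube = 1, neg = 1))

  d2 <- tibble::tibble(a = c(1, 2, 3, 4), b = c(2, 1, 4, 3))
  # 1 - 6 * sum(d^2) / (n(n^2-1)) with d^2 = (1,1,1,1): 1 - 24/60 = 0.6
  expect_equal(spearman_matrix(d2, c("a", "b"))["a", "b"], 0.6)

  d3 <- tibble::tibble(a = c(1, 2, NA, NA), b = c(2, 1, NA, NA))
  expect_true(is.na(spearman_matrix(d3, c("a", "b"))["a", "b"]))
})

test_that("exceedance counting is strict and monotone in the guideline", {
  d <- tibble::tibble(
    date = as.Date("2020-01-01") + 0:2,
    phase = factor(rep("A", 3)),
    pm25 = c(12, 16, 20),
    pm10 = c(45, 44, 46),
    o3_8h_max = c(90, 110, NA)
  )
  ex <- exceedance_frequency(d, c(pm25 = 15, pm10 = 45, o3 = 100))
  expect_equal(ex$n_exceed[ex$pollutant == "pm25"], 2)
  expect_equal(ex$fraction[ex$pollutant == "pm25"], 2 / 3)
  # a value exactly at the guideline is not an exceedance
  expect_equal(ex$n_exceed[ex$pollutant == "pm10"], 1)
  # ozone judged on the 8-h metric with valid-day denominator
  expect_equal(ex$n_valid[ex$pollutant == "o3"], 2)
  # monotone non-increasing in the guideline level
  counts <- vapply(
    c(10, 15, 20, 25),
    function(g) exceedance_frequency(d, c(pm25 = g))$n_exceed,
    integer(1)
  )
  expect_true(all(diff(counts) <= 0))
  # zero valid days: undefined fraction, flagged by NA
  d$pm25 <- NA_real_
  expect_true(is.na(exceedance_frequency(d, c(pm25 = 15))$fraction))
})

test_that("weekday-weekend contrast recovers the planted traffic signal", {
  cfg <- zero_noise_config(mini_config())
  cfg$no2_weekday_uplift <- 0.2
  # flat NO2 baseline of 5 so the planted contrast is exactly 1 ug/m3
  cfg$phase_means$no2[] <- 5
  d <- aggregate_daily(generate_scenario(cfg), 18, cfg$calendar)
  wc <- weekday_weekend_contrast(d, "no2")
  expect_equal(wc$diff[wc$ok], rep(1, sum(wc$ok)), tolerance = 1e-9)

  # no uplift: contrast ~ 0 with interval covering 0
  cfg0 <- mini_config(seed = 31L)
  cfg0$no2_weekday_uplift <- 0
  d0 <- aggregate_daily(generate_scenario(cfg0), 18, cfg0$calendar)
  wc0 <- weekday_weekend_contrast(d0, "no2")
  expect_true(all(wc0$ci_lo[wc0$ok] <= 0 & wc0$ci_hi[wc0$ok] >= 0))

  # an empty stratum is flagged, not dropped
  d1 <- d0[!d0$weekday, ]
  wc1 <- weekday_weekend_contrast(d1, "no2")
  expect_true(all(!wc1$ok))
})
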