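test_that("the log-linear risk chain evaluates exactly", {
  expect_equal(relative_risk(0.00072, 4.31), exp(0.00072 * 4.31))
  expect_equal(round(relative_risk(0.00072, 4.31), 3), 1.003)
  expect_equal(relative_risk(0.00072, -1.69), 0.9987839, tolerance = 1e-7)
  expect_equal(relative_risk(0.003, 0), 1)

  expect_equal(attributable_fraction(1), 0)
  expect_equal(attributable_fraction(2), 0.5)
  expect_equal(attributable_fraction(1.003108), 0.0030984, tolerance = 1e-4)
  expect_error(attributable_fraction(0), "positive")

  p <- hia_params()
  expect_equal(attributable_deaths(0, p), 0)
  expect_equal(
    attributable_deaths(0.003098, p),
    67167 * (120 / 1e5) * 0.003098,
    tolerance = 1e-12
  )
  expect_equal(round(attributable_deaths(0.003098, p), 4), 0.2497)
  p2 <- hia_params(population = 2 * 67167)
  expect_equal(
    attributable_deaths(0.003098, p2),
    2 * attributable_deaths(0.003098, p)
  )
})

test_that("parameter invariants are enforced at construction", {
  expect_error(hia_params(beta = 0.001, beta_ci = c(0.0001, 0.0005)))
  expect_error(hia_params(population = -1))
  expect_error(hia_params(baseline_rate = 0))
  expect_error(hia_params(mc_draws = 10))
})

test_that("first-order identities hold for small risk increments", {
  p <- hia_params()
  for (delta in c(-5, -1.69, -0.5, 0.5, 1.91, 4.31, 5)) {
    af <- attributable_fraction(relative_risk(p$beta, delta))
    expect_lt(abs(af - p$beta * delta), 1e-4)
    # deaths are odd in delta to within 0.5%
    d_pos <- attributable_deaths(
      attributable_fraction(relative_risk(p$beta, abs(delta))), p
    )
    d_neg <- attributable_deaths(
      attributable_fraction(relative_risk(p$beta, -abs(delta))), p
    )
    expect_lt(abs(d_pos + d_neg), 0.005 * abs(d_pos))
  }
})

test_that("deaths are strictly monotone in every driver", {
  af <- function(beta, delta) attributable_fraction(relative_risk(beta, delta))
  base <- attributable_deaths(af(0.00072, 2), hia_params())
  expect_gt(attributable_deaths(af(0.00072, 3), hia_params()), base)
  expect_gt(attributable_deaths(af(0.0008, 2), hia_params(beta = 0.0008,
    beta_ci = c(0.0007, 0.0009))), base)
  expect_gt(
    attributable_deaths(af(0.00072, 2), hia_params(population = 1e5)), base
  )
  expect_gt(
    attributable_deaths(af(0.00072, 2), hia_params(baseline_rate = 200)), base
  )
})

test_that("Monte Carlo interval collapses to the analytic point", {
  p <- hia_params(
    beta = 0.00072, beta_ci = c(0.00072, 0.00072), rate_cv = 0
  )
  mc <- monte_carlo_uncertainty(4.31, p)
  expect_equal(mc$lo, mc$point, tolerance = 1e-12)
  expect_equal(mc$hi, mc$point, tolerance = 1e-12)
  analytic <- attributable_deaths(
    attributable_fraction(relative_risk(0.00072, 4.31)), p
  )
  expect_equal(mc$point, analytic)
})

test_that("Monte Carlo draws are seeded and reproducible", {
  p <- hia_params(mc_seed = 77L)
  a <- monte_carlo_uncertainty(4.31, p)
  b <- monte_carlo_uncertainty(4.31, p)
  expect_identical(a, b)
  p2 <- hia_params(mc_seed = 78L)
  expect_false(identical(monte_carlo_uncertainty(4.31, p2), a))
  # interval brackets the point and widens with delta
  expect_lt(a$lo, a$point)
  expect_gt(a$hi, a$point)
})

test_that("the phase table reproduces the published concentration chain", {
  cfg <- zero_noise_config(default_ilo_config())
  daily <- aggregate_daily(generate_scenario(cfg), 18, cfg$calendar)
  tab <- hia_table(daily)
  expect_equal(as.character(tab$phase[1]), "Pre-Pandemic")
  expect_equal(tab$delta[1], 0)
  expect_equal(tab$rr[1], 1)
  expect_equal(tab$deaths[1], 0)
  # published deltas, within mean-rounding
  expect_equal(
    tab$delta,
    c(0, 1.91, 4.31, 2.44, -1.69, -0.64),
    tolerance = 0.011
  )
  expect_true(all(sign(tab$deaths) == sign(tab$delta)))
  expect_true(all(tab$rr > 0))
  expect_equal(tab$af, (tab$rr - 1) / tab$rr)
  # single-phase input: one all-zero row
  one <- daily[daily$phase == "Pre-Pandemic", ]
  one$phase <- droplevels(one$phase)
  t1 <- hia_table(one)
  expect_equal(nrow(t1), 1)
  expect_equal(t1$delta, 0)
})

test_that("risk-coefficient sensitivity scales nearly linearly", {
  cfg <- zero_noise_config(default_ilo_config())
  daily <- aggregate_daily(generate_scenario(cfg), 18, cfg$calendar)
  sens <- beta_sensitivity(
    daily,
    beta_set = c(GBD2021 = 0.00072, GBD2019 = 0.00076, Pope = 0.00080)
  )
  p1 <- sens[sens$phase == "Phase 1", ]
  ratio <- p1$deaths[p1$source == "Pope"] / p1$deaths[p1$source == "GBD2021"]
  expect_equal(ratio, 0.00080 / 0.00072, tolerance = 0.01)
  # GBD 2021 is ~5% below GBD 2019
  expect_equal(
    p1$deaths[p1$source == "GBD2021"] / p1$deaths[p1$source == "GBD2019"],
    0.00072 / 0.00076,
    tolerance = 0.01
  )
  # identical coefficients give identical rows
  same <- beta_sensitivity(daily, beta_set = c(a = 7e-4, b = 7e-4))
  expect_equal(
    same[same$source == "a", setdiff(names(same), "source")],
    same[same$source == "b", setdiff(names(same), "source")]
  )
  expect_error(beta_sensitivity(daily, beta_set = numeric()), "empty")
  expect_error(beta_sensitivity(daily, beta_set = c(x = -1e-4)), "positive")
})
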