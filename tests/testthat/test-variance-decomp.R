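make_model_daily <- function(n = 120, seed = 1, response = NULL) {
  withr::with_seed(seed, {
    d <- tibble::tibble(
      date = as.Date("2020-01-01") + seq_len(n) - 1,
      phase = factor(
        rep(c("Ref", "P1", "P2"), length.out = n),
        levels = c("Ref", "P1", "P2")
      ),
      temp = stats::rnorm(n),
      ws = stats::rnorm(n),
      rh = stats::rnorm(n)
    )
    d$y <- if (is.null(response)) stats::rnorm(n) else response(d)
    d
  })
}

test_that("noiseless meteorological response saturates the reduced model", {
  d <- make_model_daily(response = function(d) 2 + 3 * d$temp)
  fits <- fit_nested_models(d, "y")
  expect_equal(fits$m1$aqpd$r2, 1, tolerance = 1e-12)
  expect_equal(fits$m2$aqpd$r2 - fits$m1$aqpd$r2, 0, tolerance = 1e-12)
})

test_that("pure-noise responses give near-zero fits and uniform p-values", {
  ps <- vapply(1:200, function(i) {
    d <- make_model_daily(n = 60, seed = i)
    fits <- fit_nested_models(d, "y")
    nested_anova_f(fits$m1, fits$m2)$p
  }, numeric(1))
  rate <- mean(ps < 0.05)
  expect_gt(rate, 0.015)
  expect_lt(rate, 0.105)
})

test_that("variance decomposition conserves and orders its pieces", {
  for (i in 1:20) {
    d <- make_model_daily(
      n = 90, seed = 100 + i,
      response = function(d) {
        stats::rnorm(nrow(d)) + 0.5 * d$temp +
          0.5 * (d$phase == "P1")
      }
    )
    fits <- fit_nested_models(d, "y")
    dec <- decompose_variance(fits$m1, fits$m2)
    expect_gte(dec$r2_covid, -1e-12) # R2 never decreases under nesting
    expect_equal(dec$pct_meteo + dec$pct_covid, 100, tolerance = 1e-9)
    expect_equal(dec$r2_full - dec$r2_meteo, dec$r2_covid)
    expect_equal(fits$m1$aqpd$n, fits$m2$aqpd$n)
  }
})

test_that("complete cases are intersected across both models", {
  d <- make_model_daily(n = 80, seed = 7)
  d$temp[1:5] <- NA # missing in a meteorology column
  d$y[6:8] <- NA # missing in the response
  fits <- fit_nested_models(d, "y")
  expect_equal(fits$m1$aqpd$n, 80 - 8)
  expect_equal(fits$m2$aqpd$n, 80 - 8)
})

test_that("variance shares match the published ozone arithmetic and edge cases", {
  s <- variance_shares(0.800, 0.812)
  expect_equal(round(s[["pct_meteo"]], 1), 98.5)
  expect_equal(round(s[["pct_covid"]], 1), 1.5)
  expect_equal(
    variance_shares(0.3, 0.3)[["pct_covid"]], 0
  )
  expect_warning(s0 <- variance_shares(0, 0), "undefined")
  expect_true(all(is.na(s0)))
  expect_error(variance_shares(0.5, 0.4), "nested")
})

test_that("nested F matches anova() and explicit RSS arithmetic", {
  # hand-built 12-row dataset
  d <- tibble::tibble(
    y = c(3, 5, 4, 6, 8, 7, 9, 11, 10, 12, 14, 13),
    x = c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12),
    g = factor(rep(c("a", "b", "c"), each = 4))
  )
  m1 <- stats::lm(y ~ x, data = d)
  m2 <- stats::lm(y ~ x + g, data = d)
  res <- nested_anova_f(m1, m2)
  rss1 <- sum(stats::residuals(m1)^2)
  rss2 <- sum(stats::residuals(m2)^2)
  f_by_hand <- ((rss1 - rss2) / 2) / (rss2 / 8)
  expect_equal(res$f, f_by_hand, tolerance = 1e-12)
  an <- stats::anova(m1, m2) # independent oracle
  expect_equal(res$f, an$F[2], tolerance = 1e-12)
  expect_equal(res$p, an$`Pr(>F)`[2], tolerance = 1e-12)
  expect_equal(c(res$df1, res$df2), c(2, 8))
})

test_that("a zero-contribution regressor gives F = 0 and p = 1", {
  withr::with_seed(9, {
    x <- stats::rnorm(30)
    y <- 1 + 2 * x + stats::rnorm(30)
    m1 <- stats::lm(y ~ x)
    # orthogonalize a new regressor against design AND residuals so the
    # full model's RSS is unchanged
    z0 <- stats::rnorm(30)
    z <- stats::residuals(stats::lm(z0 ~ x + stats::residuals(m1)))
    m2 <- stats::lm(y ~ x + z)
    res <- nested_anova_f(m1, m2)
    expect_equal(res$f, 0, tolerance = 1e-9)
    expect_equal(res$p, 1, tolerance = 1e-9)
  })
})

test_that("adding one indicator: F equals the squared t statistic", {
  withr::with_seed(11, {
    n <- 50
    x <- stats::rnorm(n)
    g <- rep(c(0, 1), length.out = n)
    y <- 1 + x + 0.8 * g + stats::rnorm(n)
    m1 <- stats::lm(y ~ x)
    m2 <- stats::lm(y ~ x + g)
    f <- nested_anova_f(m1, m2)$f
    t_g <- summary(m2)$coefficients["g", "t value"]
    expect_equal(f, t_g^2, tolerance = 1e-10)
  })
})

test_that("VIFs are ~1 on orthogonal predictors and flag collinearity", {
  d <- make_model_daily(n = 200, seed = 13)
  fits <- fit_nested_models(d, "y")
  met_vif <- fits$m1$aqpd$vif
  expect_true(all(abs(met_vif - 1) < 0.25))
  # near-duplicate predictors inflate the VIF
  withr::with_seed(14, {
    x <- stats::rnorm(100)
    x2 <- x + stats::rnorm(100, sd = 0.05)
    y <- x + stats::rnorm(100)
    m <- stats::lm(y ~ x + x2)
    expect_true(all(model_vif(m) > 5))
  })
})

test_that("rank-deficient designs are rejected with the offending column", {
  d <- make_model_daily(n = 60, seed = 17)
  d$rh <- d$temp # exact duplicate
  expect_error(fit_nested_models(d, "y"), "collinear")
})

test_that("robust standard errors behave as sandwich theory predicts", {
  # homoscedastic: robust ~ classical
  withr::with_seed(21, {
    n <- 300
    x <- stats::rnorm(n)
    y <- 1 + x + stats::rnorm(n)
    tab <- robust_se(stats::lm(y ~ x))
    expect_true(all(abs(tab$se_robust / tab$se_classical - 1) < 0.10))
  })
  # variance growing with x^2: robust SE larger for the x coefficient
  withr::with_seed(22, {
    n <- 400
    x <- stats::rnorm(n)
    y <- 1 + x + stats::rnorm(n, sd = abs(x))
    tab <- robust_se(stats::lm(y ~ x))
    expect_gt(tab$se_robust[2], tab$se_classical[2])
  })
  # duplicating every row halves the sampling variance, not the estimates
  withr::with_seed(23, {
    n <- 150
    d <- data.frame(x = stats::rnorm(n))
    d$y <- 1 + d$x + stats::rnorm(n)
    t1 <- robust_se(stats::lm(y ~ x, d))
    t2 <- robust_se(stats::lm(y ~ x, rbind(d, d)))
    expect_equal(t2$estimate, t1$estimate, tolerance = 1e-12)
    expect_equal(
      t2$se_classical / t1$se_classical, rep(1 / sqrt(2), 2),
      tolerance = 0.02
    )
  })
  # leverage-one rows make HC3 undefined
  d <- data.frame(x = c(0, 0, 0, 1), y = c(1, 2, 3, 9))
  expect_error(robust_se(stats::lm(y ~ x, d)), "leverage")
})
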