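#' Fit the nested meteorology-only and full models for one pollutant
#'
#' Fits, by ordinary least squares on the identical complete-case row set,
#'
#' * M1 (meteorology only): `Y ~ temp + ws + rh`
#' * M2 (full): `Y ~ temp + ws + rh + phase`
#'
#' where the meteorological predictors are standardized over the full
#' analysis window (so coefficients are comparable across phases) and phase
#' enters as indicators against the calendar's reference phase. Complete
#' cases are intersected across the response, all meteorology variables, and
#' phase *before* either fit, so the two R-squared values are computed on the
#' same sample and their difference is a valid variance increment.
#'
#' Variance inflation factors are computed per model-matrix column as
#' `1 / (1 - R2_j)` (column j regressed on the remaining columns); a value
#' above 5 triggers a collinearity warning.
#'
#' @param daily Daily dataset with `phase` ([aggregate_daily()] with a
#'   calendar).
#' @param pollutant Response column.
#' @param meteorology_vars Continuous predictors; default
#'   `c("temp", "ws", "rh")`, extendable with `"pres"`, `"rad"`.
#' @return A list with elements `m1` and `m2`, each an `lm` fit carrying
#'   `$aqpd` metadata (`pollutant`, `n`, `r2`, `rss`, `vif`, `scaling`).
#' @export
fit_nested_models <- function(daily, pollutant,
                              meteorology_vars = c("temp", "ws", "rh")) {
  stopifnot(
    pollutant %in% names(daily),
    all(meteorology_vars %in% names(daily)),
    "phase" %in% names(daily)
  )
  std <- standardize_predictors(daily, meteorology_vars)
  d <- std$data
  keep <- stats::complete.cases(
    d[, c(pollutant, meteorology_vars, "phase")]
  )
  d <- d[keep, , drop = FALSE]
  d$phase <- droplevels(d$phase)
  n_coef <- 1 + length(meteorology_vars) + nlevels(d$phase) - 1
  if (nrow(d) < 3 + n_coef) {
    stop("too few complete-case rows (", nrow(d), ") for ", pollutant,
      call. = FALSE
    )
  }
  f1 <- stats::reformulate(meteorology_vars, response = pollutant)
  f2 <- stats::reformulate(c(meteorology_vars, "phase"), response = pollutant)
  m1 <- stats::lm(f1, data = d)
  m2 <- stats::lm(f2, data = d)
  for (m in list(m1, m2)) {
    if (any(is.na(stats::coef(m)))) {
      bad <- names(stats::coef(m))[is.na(stats::coef(m))]
      stop("rank-deficient design; collinear column(s): ",
        paste(bad, collapse = ", "),
        call. = FALSE
      )
    }
  }
  decorate <- function(m, tag) {
    m$aqpd <- list(
      pollutant = pollutant, model = tag, n = nrow(d),
      r2 = summary(m)$r.squared,
      rss = sum(stats::residuals(m)^2),
      df_residual = stats::df.residual(m),
      vif = model_vif(m),
      scaling = std$scaling
    )
    if (any(m$aqpd$vif > 5, na.rm = TRUE)) {
      warning("VIF > 5 in ", tag, " for ", pollutant, ": ",
        paste(names(m$aqpd$vif)[m$aqpd$vif > 5], collapse = ", "),
        call. = FALSE
      )
    }
    m
  }
  list(m1 = decorate(m1, "M1"), m2 = decorate(m2, "M2"))
}

#' Variance inflation factors of a fitted linear model
#'
#' Classical per-column VIF, `1/(1 - R2_j)`, computed on the model matrix
#' without the intercept.
#'
#' @param fit An `lm` object.
#' @return Named numeric vector of VIFs.
#' @export
model_vif <- function(fit) {
  x <- stats::model.matrix(fit)
  x <- x[, colnames(x) != "(Intercept)", drop = FALSE]
  if (ncol(x) < 2) {
    return(stats::setNames(rep(1, ncol(x)), colnames(x)))
  }
  out <- numeric(ncol(x))
  for (j in seq_len(ncol(x))) {
    fit_j <- stats::lm.fit(
      cbind(`(Intercept)` = 1, x[, -j, drop = FALSE]), x[, j]
    )
    rss <- sum(fit_j$residuals^2)
    tss <- sum((x[, j] - mean(x[, j]))^2)
    r2_j <- if (tss == 0) NA_real_ else 1 - rss / tss
    out[j] <- if (is.na(r2_j) || r2_j >= 1) Inf else 1 / (1 - r2_j)
  }
  stats::setNames(out, colnames(x))
}

#' Partition explained variance between meteorology and phases
#'
#' Given the nested fits, computes `R2_meteo = R2(M1)`,
#' `R2_covid = R2(M2) - R2(M1)`, and the percentage split of the full model's
#' explained variance, `%meteo = 100 * R2_meteo / R2(M2)` and
#' `%covid = 100 * R2_covid / R2(M2)`, together with the nested ANOVA F test
#' of the phase increment. Percentages are undefined (missing, with a
#' warning) when the full model explains nothing.
#'
#' @param m1,m2 Nested fits from [fit_nested_models()] (`m1` predictors must
#'   be a subset of `m2`'s, same rows).
#' @return A one-row tibble `pollutant, n, r2_full, r2_meteo, r2_covid,
#'   pct_meteo, pct_covid, f, df1, df2, p`.
#' @export
decompose_variance <- function(m1, m2) {
  stopifnot(!is.null(m1$aqpd), !is.null(m2$aqpd))
  if (m1$aqpd$n != m2$aqpd$n) {
    stop("models were fitted on different row sets", call. = FALSE)
  }
  r2_full <- m2$aqpd$r2
  r2_meteo <- m1$aqpd$r2
  shares <- variance_shares(r2_meteo, r2_full)
  ftest <- nested_anova_f(m1, m2)
  tibble::tibble(
    pollutant = m2$aqpd$pollutant,
    n = m2$aqpd$n,
    r2_full = r2_full,
    r2_meteo = r2_meteo,
    r2_covid = r2_full - r2_meteo,
    pct_meteo = shares[["pct_meteo"]],
    pct_covid = shares[["pct_covid"]],
    f = ftest$f, df1 = ftest$df1, df2 = ftest$df2, p = ftest$p
  )
}

#' Percentage split of explained variance
#'
#' The elementary arithmetic behind [decompose_variance()]:
#' `pct_meteo = 100 * r2_meteo / r2_full` and
#' `pct_covid = 100 * (r2_full - r2_meteo) / r2_full`.
#'
#' @param r2_meteo R-squared of the meteorology-only model.
#' @param r2_full R-squared of the full model (`>= r2_meteo`).
#' @return Named numeric `c(pct_meteo =, pct_covid =)`.
#' @export
variance_shares <- function(r2_meteo, r2_full) {
  stopifnot(r2_meteo >= 0, r2_full <= 1)
  if (r2_full < r2_meteo) {
    stop("r2_full must be >= r2_meteo (nested models)", call. = FALSE)
  }
  if (r2_full == 0) {
    warning("full model explains no variance; shares undefined",
      call. = FALSE
    )
    return(c(pct_meteo = NA_real_, pct_covid = NA_real_))
  }
  c(
    pct_meteo = 100 * r2_meteo / r2_full,
    pct_covid = 100 * (r2_full - r2_meteo) / r2_full
  )
}

#' Nested ANOVA F test
#'
#' `F = ((RSS1 - RSS2)/q) / (RSS2/df2)` where `q` is the number of regressors
#' added in the full model and `df2` its residual degrees of freedom; the
#' p-value comes from the F(q, df2) distribution.
#'
#' @param m1 Reduced model (`lm`).
#' @param m2 Full model (`lm`), containing `m1`'s regressors.
#' @return A list `f, df1, df2, p`.
#' @export
nested_anova_f <- function(m1, m2) {
  rss1 <- sum(stats::residuals(m1)^2)
  rss2 <- sum(stats::residuals(m2)^2)
  q <- stats::df.residual(m1) - stats::df.residual(m2)
  df2 <- stats::df.residual(m2)
  if (df2 <= 0) stop("full model has no residual df", call. = FALSE)
  if (q <= 0) stop("m2 must add regressors beyond m1", call. = FALSE)
  f <- ((rss1 - rss2) / q) / (rss2 / df2)
  list(f = f, df1 = q, df2 = df2, p = stats::pf(f, q, df2, lower.tail = FALSE))
}

#' Heteroscedasticity-robust coefficient standard errors
#'
#' Sandwich (White-family) standard errors for a fitted model, HC3 by
#' default, returned alongside the classical OLS ones.
#'
#' @param fit An `lm` object.
#' @param flavor One of `"HC3"`, `"HC0"`, `"HC1"`, `"HC2"`.
#' @return A tibble `term, estimate, se_classical, se_robust`.
#' @export
robust_se <- function(fit, flavor = c("HC3", "HC0", "HC1", "HC2")) {
  flavor <- match.arg(flavor)
  h <- stats::hatvalues(fit)
  if (flavor %in% c("HC2", "HC3") && any(h >= 1 - 1e-12)) {
    stop(
      "leverage = 1 at row(s) ",
      paste(which(h >= 1 - 1e-12), collapse = ", "),
      "; ", flavor, " undefined",
      call. = FALSE
    )
  }
  v <- sandwich::vcovHC(fit, type = flavor)
  tibble::tibble(
    term = names(stats::coef(fit)),
    estimate = unname(stats::coef(fit)),
    se_classical = unname(sqrt(diag(stats::vcov(fit)))),
    se_robust = unname(sqrt(diag(v)))
  )
}

#' Coefficient table with classical and robust inference
#'
#' @param fit An `lm` fit (typically from [fit_nested_models()]).
#' @param flavor Robust flavor passed to [robust_se()].
#' @return A tibble `term, estimate, se_classical, se_robust, t_robust,
#'   p_robust, ci_lo, ci_hi` (robust 95% normal interval).
#' @export
coefficient_table <- function(fit, flavor = "HC3") {
  tab <- robust_se(fit, flavor)
  tab$t_robust <- tab$estimate / tab$se_robust
  tab$p_robust <- 2 * stats::pt(
    -abs(tab$t_robust), stats::df.residual(fit)
  )
  tab$ci_lo <- tab$estimate - 1.96 * tab$se_robust
  tab$ci_hi <- tab$estimate + 1.96 * tab$se_robust
  tab
}
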