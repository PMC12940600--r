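#' Random-forest specification
#'
#' Hyperparameters for the nonparametric cross-check forest: 500 regression
#' trees, `mtry = max(1, floor(p/3))` (the regression default; with the four
#' standard predictors this is 1), minimum node size 5, seed 123. The phase
#' enters as a single categorical predictor with native multiway splits.
#'
#' @param n_trees Number of trees (>= 1).
#' @param m_try Predictors tried per split; `NULL` for `max(1, floor(p/3))`.
#' @param min_node_size Minimum terminal node size.
#' @param seed Integer seed; identical seeds give identical importances.
#' @param predictors Predictor columns (phase included).
#' @return A list of class `forest_spec`.
#' @export
forest_spec <- function(n_trees = 500L, m_try = NULL, min_node_size = 5L,
                        seed = 123L,
                        predictors = c("temp", "ws", "rh", "phase")) {
  stopifnot(n_trees >= 1L, min_node_size >= 1L)
  structure(
    list(
      n_trees = as.integer(n_trees), m_try = m_try,
      min_node_size = as.integer(min_node_size), seed = as.integer(seed),
      predictors = predictors
    ),
    class = "forest_spec"
  )
}

#' Fit the variable-importance forest for one pollutant
#'
#' Bootstrap-aggregated regression trees on the complete-case rows, with
#' out-of-bag (OOB) error as internal validation and two importance
#' measures: permutation importance (%IncMSE, the OOB mean-squared-error
#' increase when a predictor is permuted, normalized by the SD of the
#' per-tree differences) and total node-impurity decrease (IncNodePurity).
#'
#' @param daily Daily dataset with `phase`.
#' @param pollutant Response column.
#' @param spec A [forest_spec()].
#' @return A list: `fit` (the `randomForest` object), `importance` (tibble
#'   `predictor, pct_inc_mse, inc_mse_raw, inc_mse_pct_of_oob,
#'   inc_node_purity`, where `pct_inc_mse` is the SD-scaled permutation
#'   measure and `inc_mse_raw` the unscaled OOB MSE increase, also expressed
#'   as a percentage of the OOB MSE), `oob_mse`, `oob_r2`, `n`, and `spec`.
#' @export
fit_forest <- function(daily, pollutant, spec = forest_spec()) {
  stopifnot(inherits(spec, "forest_spec"), pollutant %in% names(daily))
  vars <- spec$predictors
  stopifnot(all(vars %in% names(daily)))
  keep <- stats::complete.cases(daily[, c(pollutant, vars)])
  d <- as.data.frame(daily[keep, c(pollutant, vars)])
  if ("phase" %in% vars) d$phase <- droplevels(d$phase)
  if (nrow(d) < 30) {
    stop("need >= 30 complete-case rows, got ", nrow(d), call. = FALSE)
  }
  if (length(unique(d[[pollutant]])) < 2) {
    stop("constant response", call. = FALSE)
  }
  p <- length(vars)
  m_try <- if (is.null(spec$m_try)) max(1L, floor(p / 3)) else spec$m_try
  stopifnot(m_try >= 1L, m_try <= p)
  fit <- withr::with_seed(spec$seed, randomForest::randomForest(
    x = d[, vars, drop = FALSE], y = d[[pollutant]],
    ntree = spec$n_trees, mtry = m_try, nodesize = spec$min_node_size,
    importance = TRUE
  ))
  imp <- randomForest::importance(fit) # scaled permutation measure
  imp_raw <- randomForest::importance(fit, scale = FALSE)
  oob_mse <- unname(fit$mse[spec$n_trees])
  importance <- tibble::tibble(
    predictor = rownames(imp),
    pct_inc_mse = unname(imp[, "%IncMSE"]),
    inc_mse_raw = unname(imp_raw[, "%IncMSE"]),
    inc_mse_pct_of_oob = 100 * unname(imp_raw[, "%IncMSE"]) / oob_mse,
    inc_node_purity = unname(imp[, "IncNodePurity"])
  )
  list(
    fit = fit,
    importance = importance,
    oob_mse = oob_mse,
    oob_r2 = unname(fit$rsq[spec$n_trees]),
    n = nrow(d),
    spec = spec
  )
}

#' Concordance between forest importance and regression decomposition
#'
#' Compares which driver family -- meteorology or intervention phase --
#' dominates according to (a) the forest's permutation importance (share of
#' the combined positive %IncMSE carried by meteorological predictors) and
#' (b) the nested-regression variance split (`pct_meteo`). When the forest
#' explains essentially nothing out of bag (OOB R-squared below
#' `min_oob_r2`) the comparison is flagged indeterminate.
#'
#' @param forest Result of [fit_forest()].
#' @param decomposition One-row result of [decompose_variance()] for the same
#'   pollutant and rows.
#' @param min_oob_r2 OOB R-squared below which the verdict is
#'   "indeterminate"; default 0.05.
#' @return A one-row tibble `pollutant, met_share_rf, pct_meteo_reg,
#'   rf_meteo_dominant, reg_meteo_dominant, concordance`.
#' @export
compare_importance <- function(forest, decomposition, min_oob_r2 = 0.05) {
  imp <- forest$importance
  met <- imp$predictor != "phase"
  pos <- pmax(imp$pct_inc_mse, 0)
  total <- sum(pos)
  met_share <- if (total > 0) sum(pos[met]) / total else NA_real_
  indeterminate <- is.na(forest$oob_r2) || forest$oob_r2 < min_oob_r2 ||
    total == 0 || is.na(decomposition$pct_meteo)
  rf_dom <- !indeterminate && met_share > 0.5
  reg_dom <- !indeterminate && decomposition$pct_meteo > 50
  tibble::tibble(
    pollutant = decomposition$pollutant,
    met_share_rf = met_share,
    pct_meteo_reg = decomposition$pct_meteo,
    rf_meteo_dominant = if (indeterminate) NA else rf_dom,
    reg_meteo_dominant = if (indeterminate) NA else reg_dom,
    concordance = if (indeterminate) {
      "indeterminate"
    } else if (rf_dom == reg_dom) {
      "agree"
    } else {
      "disagree"
    }
  )
}
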