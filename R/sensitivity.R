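# Deterministic one-way sensitivity analysis, threshold search, tornado
# ranking, and probabilistic sensitivity analysis with acceptability curves.

# Fast paired evaluation used by sweeps, bisection and the tornado: totals
# for both strategies without trace bookkeeping.
strategy_totals <- function(params) {
  vapply(STRATEGIES, function(s) {
    r <- do.call(engine_run, engine_args(params, s))
    c(cost = r$total_cost, qalys = r$total_qalys)
  }, numeric(2))
}

# Signed decision quantities (operative minus non-operative): a sign change
# marks the decision flip for the respective criterion.
decision_margin <- function(params, wtp, criterion) {
  tt <- strategy_totals(params)
  dc <- tt["cost", "operative"] - tt["cost", "non_operative"]
  dq <- tt["qalys", "operative"] - tt["qalys", "non_operative"]
  switch(criterion,
         cost_parity = -dc,              # > 0 when operative is cheaper
         nmb_flip = wtp * dq - dc)       # > 0 when operative has higher NMB
}

#' One-way deterministic sweep of a model parameter
#'
#' Evaluates the full model at `n_points` equally spaced values of one
#' parameter, all others held at their base-case values.
#'
#' @param params An [ats_parameters()] object.
#' @param parameter Dotted parameter path (see [param_set()]), e.g.
#'   `"episode_costs.operative.hospitalization"`.
#' @param low,high Sweep range (`low <= high`; every value must satisfy the
#'   parameter set's invariants).
#' @param n_points Number of grid points (default 21).
#' @param wtp Willingness-to-pay used for the preferred-strategy column
#'   (default: smallest value of the run-settings grid).
#' @return A tibble with one row per grid value: `parameter`, `value`,
#'   per-strategy costs and QALYs, `delta_cost`, `delta_qalys` (operative
#'   minus non-operative), `nmb_difference` and `preferred` at `wtp`.
#' @export
one_way_sweep <- function(params, parameter, low, high, n_points = 21,
                          wtp = NULL) {
  if (low > high) abort("one_way_sweep(): need low <= high.")
  wtp <- wtp %||% min(params$settings$wtp_grid)
  # fail before any evaluation if either endpoint violates an invariant
  param_set(params, parameter, low)
  param_set(params, parameter, high)
  values <- if (n_points == 1) (low + high) / 2 else seq(low, high, length.out = n_points)
  purrr::map_dfr(values, function(v) {
    tt <- strategy_totals(param_set(params, parameter, v))
    dc <- tt["cost", "operative"] - tt["cost", "non_operative"]
    dq <- tt["qalys", "operative"] - tt["qalys", "non_operative"]
    nd <- wtp * dq - dc
    tibble(parameter = parameter, value = v,
           cost_nonoperative = tt["cost", "non_operative"],
           cost_operative = tt["cost", "operative"],
           qalys_nonoperative = tt["qalys", "non_operative"],
           qalys_operative = tt["qalys", "operative"],
           delta_cost = dc, delta_qalys = dq, nmb_difference = nd,
           preferred = ifelse(nd > NMB_TIE_TOL, "operative", "non_operative"))
  })
}

# money-like paths get a $0.01 bisection tolerance; probabilities, utilities
# and the like get 1e-4
default_threshold_tol <- function(parameter) {
  money <- grepl("^(episode_costs\\..*\\.(hospitalization|surgeon|physical_therapy)|complication_costs\\.|wage\\.hourly_wage)",
                 parameter)
  if (money) 0.01 else 1e-4
}

#' Find the decision threshold of one parameter
#'
#' Bisects one model parameter to the value at which the preferred strategy
#' changes, under one of two criteria: `"nmb_flip"` (the net-monetary-benefit
#' ranking at `wtp` flips) or `"cost_parity"` (the two strategies' total
#' expected costs become equal). The published flip points for hospitalization
#' cost and hourly wage behave as cost parity, which is therefore the default
#' criterion.
#'
#' @inheritParams one_way_sweep
#' @param bounds Length-2 numeric search interval; the decision must differ
#'   at its two ends.
#' @param criterion `"cost_parity"` (default) or `"nmb_flip"`.
#' @param tol Absolute bisection tolerance; defaults to $0.01 for money
#'   parameters and 1e-4 otherwise.
#' @return A one-row tibble: `parameter`, `criterion`, `wtp`, `threshold`,
#'   `margin_low`, `margin_high` (signed operative-minus-non-operative
#'   decision margins at the bounds) and `operative_preferred_when`
#'   (`"below"` or `"above"` the threshold).
#' @examples
#' p <- base_case_parameters()
#' find_threshold(p, "episode_costs.operative.hospitalization",
#'                bounds = c(0, 3145))                    # ~2621.66
#' @export
find_threshold <- function(params, parameter, bounds, wtp = NULL,
                           criterion = c("cost_parity", "nmb_flip"),
                           tol = NULL) {
  criterion <- match.arg(criterion)
  wtp <- wtp %||% min(params$settings$wtp_grid)
  tol <- tol %||% default_threshold_tol(parameter)
  lo <- min(bounds); hi <- max(bounds)
  f <- function(v) decision_margin(param_set(params, parameter, v), wtp, criterion)
  m_lo <- f(lo); m_hi <- f(hi)
  if (sign(m_lo) == sign(m_hi)) {
    abort(sprintf("find_threshold(): no threshold in range [%g, %g] for '%s' (margins %.4f and %.4f).",
                  lo, hi, parameter, m_lo, m_hi))
  }
  a <- lo; b <- hi; fa <- m_lo
  while ((b - a) > tol) {
    mid <- (a + b) / 2
    fm <- f(mid)
    if (fm == 0 || sign(fm) == sign(fa)) { a <- mid; fa <- fm } else b <- mid
  }
  threshold <- (a + b) / 2
  tibble(parameter = parameter, criterion = criterion, wtp = wtp,
         threshold = threshold, margin_low = m_lo, margin_high = m_hi,
         operative_preferred_when = if (m_lo > 0) "below" else "above")
}

#' Tornado ranking of parameter influence
#'
#' Evaluates the net-monetary-benefit difference (operative minus
#' non-operative, at `wtp`) at the low and high end of each parameter's
#' plausible range and ranks parameters by the width of the induced swing.
#'
#' @inheritParams one_way_sweep
#' @param specs A data frame with columns `parameter`, `low`, `high`.
#' @return A tibble ranked by decreasing swing: `parameter`, `low`, `high`,
#'   `nmb_difference_low`, `nmb_difference_high`, `nmb_difference_base`,
#'   `swing`, plus the preferred strategy at each end.
#' @export
tornado <- function(params, specs, wtp = NULL) {
  if (nrow(specs) < 1) abort("tornado(): need at least one sweep specification.")
  wtp <- wtp %||% min(params$settings$wtp_grid)
  base_margin <- decision_margin(params, wtp, "nmb_flip")
  out <- purrr::pmap_dfr(specs[, c("parameter", "low", "high")], function(parameter, low, high) {
    m_lo <- decision_margin(param_set(params, parameter, low), wtp, "nmb_flip")
    m_hi <- decision_margin(param_set(params, parameter, high), wtp, "nmb_flip")
    tibble(parameter = parameter, low = low, high = high,
           nmb_difference_low = m_lo, nmb_difference_high = m_hi,
           nmb_difference_base = base_margin,
           swing = abs(m_hi - m_lo),
           preferred_at_low = ifelse(m_lo > NMB_TIE_TOL, "operative", "non_operative"),
           preferred_at_high = ifelse(m_hi > NMB_TIE_TOL, "operative", "non_operative"))
  })
  dplyr::arrange(out, dplyr::desc(.data$swing))
}
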