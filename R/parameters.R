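#' Per-episode event rates
#'
#' Bundle the three per-treatment-episode event probabilities used by the
#' cohort model: re-rupture of the repaired tendon, a major complication
#' (deep venous thrombosis, pulmonary embolism, deep infection, sural nerve
#' injury) and a minor complication (superficial infection, transient pain,
#' painful or hypertrophic scar). The remainder of the episode mass goes to
#' full benefit.
#'
#' @param rerupture,major,minor Probabilities per treatment episode, each in
#'   `[0, 1]` and jointly summing to less than 1.
#' @return A named numeric vector of length 3 with names
#'   `c("rerupture", "major", "minor")`.
#' @examples
#' event_rates(0.096, 0.031, 0.043)
#' @export
event_rates <- function(rerupture, major, minor) {
  r <- c(rerupture = as.numeric(rerupture), major = as.numeric(major),
         minor = as.numeric(minor))
  check_event_rates(r, "event_rates()")
  r
}

check_event_rates <- function(r, where) {
  if (any(!is.finite(r)) || any(r < 0) || any(r > 1)) {
    abort(sprintf("%s: each event probability must be a finite value in [0, 1].",
                  where))
  }
  if (sum(r) >= 1) {
    abort(sprintf(
      "%s: event probabilities sum to %.4f; they must sum to < 1 (offending rates: %s).",
      where, sum(r), paste(sprintf("%s = %.4f", names(r), r), collapse = ", ")))
  }
  invisible(r)
}

#' Relative risks of treatment events, operative versus non-operative
#'
#' @param events Character vector of event labels (subset of
#'   `"rerupture"`, `"major"`, `"minor"`).
#' @param point Point estimates of the risk ratios.
#' @param ci_low,ci_high 95% confidence bounds, `0 < ci_low <= point <= ci_high`.
#' @return A tibble with one row per event.
#' @examples
#' relative_risks(
#'   events  = c("rerupture", "major", "minor"),
#'   point   = c(0.40, 1.79, 3.54),
#'   ci_low  = c(0.12, 0.64, 0.40),
#'   ci_high = c(1.32, 5.01, 31.61)
#' )
#' @export
relative_risks <- function(events, point, ci_low, ci_high) {
  rr <- tibble(event = as.character(events), point = as.numeric(point),
               ci_low = as.numeric(ci_low), ci_high = as.numeric(ci_high))
  if (!all(rr$event %in% EVENTS)) {
    abort("relative_risks(): events must be among 'rerupture', 'major', 'minor'.")
  }
  bad <- !(rr$ci_low > 0 & rr$ci_low <= rr$point & rr$point <= rr$ci_high)
  if (any(bad)) {
    abort(sprintf("relative_risks(): need 0 < ci_low <= point <= ci_high (violated for %s).",
                  paste(rr$event[bad], collapse = ", ")))
  }
  rr
}

#' Derive operative event rates from relative risks
#'
#' Multiplies each non-operative event probability by the corresponding risk
#' ratio (operative versus non-operative), clipping each product to `[0, 1]`.
#'
#' @param rr A tibble from [relative_risks()] containing all three events, or
#'   a named numeric vector of point risk ratios.
#' @param nonop Non-operative [event_rates()].
#' @return A named numeric vector of operative event rates.
#' @examples
#' rr <- relative_risks(c("rerupture", "major", "minor"),
#'                      c(0.40, 1.79, 3.54), c(0.12, 0.64, 0.40),
#'                      c(1.32, 5.01, 31.61))
#' derive_operative_rates(rr, event_rates(0.096, 0.031, 0.043))
#' @export
derive_operative_rates <- function(rr, nonop) {
  pts <- if (is.data.frame(rr)) setNames(rr$point, rr$event) else rr
  if (!all(EVENTS %in% names(pts))) {
    abort("derive_operative_rates(): risk ratios must cover rerupture, major and minor events.")
  }
  if (any(pts[EVENTS] <= 0)) abort("derive_operative_rates(): risk ratios must be > 0.")
  out <- pmin(pmax(pts[EVENTS] * nonop[EVENTS], 0), 1)
  if (sum(out) >= 1) {
    abort(sprintf(
      "derive_operative_rates(): derived rates sum to %.4f >= 1 (%s).",
      sum(out), paste(sprintf("%s = %.4f", names(out), out), collapse = ", ")))
  }
  out
}

#' Episode cost components
#'
#' Direct and indirect cost components of one treatment episode. Missed-work
#' cost is not stored: it is always derived from the episode's weeks off work
#' and the wage model, so that wage sweeps propagate coherently.
#'
#' @param episode One of `"operative"`, `"non_operative"`, `"rerupture_surgery"`.
#' @param hospitalization,surgeon,physical_therapy Costs in 2014 USD.
#' @param weeks_missed Weeks off work attributed to the episode.
#' @return A one-row tibble.
#' @export
episode_costs <- function(episode, hospitalization, surgeon, physical_therapy,
                          weeks_missed) {
  episode <- match.arg(episode, EPISODES)
  x <- c(hospitalization = hospitalization, surgeon = surgeon,
         physical_therapy = physical_therapy, weeks_missed = weeks_missed)
  if (any(!is.finite(x)) || any(x < 0)) {
    abort("episode_costs(): all components must be finite and >= 0.")
  }
  if (episode == "non_operative" && hospitalization != 0) {
    abort("episode_costs(): the non-operative episode has no hospitalization cost.")
  }
  tibble(episode = episode, hospitalization = hospitalization, surgeon = surgeon,
         physical_therapy = physical_therapy, weeks_missed = weeks_missed)
}

#' Wage model for indirect (missed-work) costs
#'
#' @param hourly_wage 2014 USD per hour.
#' @param hours_per_week Working hours per week (default 40).
#' @return A list of class-free wage parameters.
#' @export
wage_model <- function(hourly_wage, hours_per_week = 40) {
  if (hourly_wage < 0 || hours_per_week < 0) {
    abort("wage_model(): wage and hours must be >= 0.")
  }
  list(hourly_wage = as.numeric(hourly_wage),
       hours_per_week = as.numeric(hours_per_week))
}

#' Indirect cost of missed work
#'
#' @param weeks Weeks off work (>= 0).
#' @param wage A [wage_model()].
#' @return Cost in USD: `weeks * hours_per_week * hourly_wage`.
#' @examples
#' missed_work_cost(8, wage_model(24.48125))      # 7834
#' missed_work_cost(10.5, wage_model(24.48125))   # 10282.125
#' @export
missed_work_cost <- function(weeks, wage) {
  if (any(weeks < 0)) abort("missed_work_cost(): weeks must be >= 0.")
  weeks * wage$hours_per_week * wage$hourly_wage
}

#' Hourly wage implied by a missed-work cost
#'
#' Inverse of [missed_work_cost()]; used to back the hourly wage out of a
#' printed missed-work total.
#'
#' @param missed_work Missed-work cost in USD.
#' @param weeks Weeks off work (> 0).
#' @param hours_per_week Hours per week (> 0).
#' @return USD per hour.
#' @examples
#' implied_hourly_wage(7834, 8)     # 24.48125
#' implied_hourly_wage(10282, 10.5) # 24.48095...
#' @export
implied_hourly_wage <- function(missed_work, weeks, hours_per_week = 40) {
  if (weeks <= 0 || hours_per_week <= 0) {
    abort("implied_hourly_wage(): weeks and hours_per_week must be > 0.")
  }
  missed_work / (weeks * hours_per_week)
}

#' Total cost of one treatment episode
#'
#' Sums hospitalization, surgeon and physical-therapy fees plus (optionally)
#' the wage-derived missed-work cost for one episode kind.
#'
#' @param params An [ats_parameters()] object.
#' @param episode Episode kind; one of `"operative"`, `"non_operative"`,
#'   `"rerupture_surgery"`.
#' @param include_missed_work Include the indirect missed-work component
#'   (default `TRUE`, the societal perspective).
#' @return Total episode cost in 2014 USD.
#' @examples
#' p <- base_case_parameters(calibrated = FALSE)
#' episode_cost_total(p, "operative")       # ~12,610 (printed total 12,609)
#' episode_cost_total(p, "non_operative")   # ~11,386
#' @export
episode_cost_total <- function(params, episode, include_missed_work = TRUE) {
  episode <- match.arg(episode, EPISODES)
  row <- params$episode_costs[params$episode_costs$episode == episode, ]
  direct <- row$hospitalization + row$surgeon + row$physical_therapy
  if (include_missed_work) {
    direct <- direct + missed_work_cost(row$weeks_missed, params$wage)
  }
  direct
}

#' Per-cycle utility schedule and complication decrements
#'
#' Utilities are time-dependent: cycles since the most recent treatment index
#' into `recovery` (0.7 in the first three months, 0.8 in the next, 0.9
#' thereafter in the base case). Minor and major complications multiply the
#' scheduled utility by `minor_multiplier` and `major_multiplier`.
#' `nonoperative_ratio` proportionally scales every utility accrued by the
#' non-operative cohort; the base case assumes equal quality of life between
#' arms (ratio 1).
#'
#' @param recovery Non-decreasing utilities in `[0, 1]`, indexed by cycles
#'   since last treatment; the last entry persists to the horizon.
#' @param minor_multiplier,major_multiplier Multiplicative decrements in
#'   `(0, 1]`.
#' @param nonoperative_ratio Ratio of non-operative to operative utilities.
#' @param complication_persistence `"horizon"` (complication states absorb to
#'   the end of the model, the default) or `"single_cycle"` (the decrement
#'   applies only in the cycle the complication arises, after which the
#'   cohort rejoins full benefit).
#' @return A list of utility parameters.
#' @export
utility_schedule <- function(recovery = c(0.7, 0.8, 0.9),
                             minor_multiplier = 0.9,
                             major_multiplier = 0.8,
                             nonoperative_ratio = 1,
                             complication_persistence = c("horizon", "single_cycle")) {
  complication_persistence <- match.arg(complication_persistence)
  if (any(recovery < 0) || any(recovery > 1)) {
    abort("utility_schedule(): recovery utilities must lie in [0, 1].")
  }
  if (is.unsorted(recovery)) {
    abort("utility_schedule(): recovery utilities must be non-decreasing.")
  }
  for (m in c(minor_multiplier, major_multiplier)) {
    if (m <= 0 || m > 1) abort("utility_schedule(): multipliers must lie in (0, 1].")
  }
  if (nonoperative_ratio < 0) abort("utility_schedule(): nonoperative_ratio must be >= 0.")
  list(recovery = as.numeric(recovery),
       full_benefit = recovery[length(recovery)],
       minor_multiplier = minor_multiplier,
       major_multiplier = major_multiplier,
       nonoperative_ratio = nonoperative_ratio,
       complication_persistence = complication_persistence)
}

#' Run settings of the cohort model
#'
#' @param cycle_length Cycle length in years (default 0.25, i.e. 3 months).
#' @param n_cycles Number of cycles (default 8; horizon = 2 years).
#' @param discount_rate Annual discount rate (default 0: the short horizon is
#'   not discounted).
#' @param wtp_grid Willingness-to-pay thresholds in USD per QALY.
#' @param psa_iterations Monte Carlo iterations for probabilistic sensitivity
#'   analysis.
#' @param seed Optional default RNG seed for the PSA.
#' @return A list of run settings.
#' @export
run_settings <- function(cycle_length = 0.25, n_cycles = 8, discount_rate = 0,
                         wtp_grid = c(50000, 100000), psa_iterations = 10000,
                         seed = NULL) {
  if (cycle_length <= 0 || n_cycles < 1) {
    abort("run_settings(): need cycle_length > 0 and n_cycles >= 1.")
  }
  if (discount_rate < 0) abort("run_settings(): discount_rate must be >= 0.")
  if (psa_iterations < 1) abort("run_settings(): psa_iterations must be >= 1.")
  list(cycle_length = cycle_length, n_cycles = as.integer(n_cycles),
       horizon = cycle_length * n_cycles, discount_rate = discount_rate,
       wtp_grid = as.numeric(wtp_grid), psa_iterations = as.integer(psa_iterations),
       seed = seed)
}

#' Assemble a complete model parameter set
#'
#' The single input object of the cost-utility model: event rates for both
#' strategies (operative rates either given verbatim or derived from the risk
#' ratios), episode cost components, the wage model behind every missed-work
#' cost, complication event costs, the utility schedule and run settings.
#'
#' @param rates_nonoperative Non-operative [event_rates()].
#' @param relative_risks Risk-ratio tibble from [relative_risks()].
#' @param rates_operative Operative [event_rates()], or `NULL` to derive them
#'   as risk ratio times the non-operative rate.
#' @param episode_costs Tibble binding three [episode_costs()] rows (one per
#'   episode kind).
#' @param complication_costs Named list or vector with elements `major` and
#'   `minor`: one-off costs charged when the respective complication arises.
#' @param wage A [wage_model()].
#' @param utilities A [utility_schedule()].
#' @param settings A [run_settings()].
#' @param hospitalization_ci Optional `c(low, high)` 95% CI of the operative
#'   hospitalization cost (used to set its PSA spread).
#' @param complication_cost_source `"user"` or `"calibrated"`; bookkeeping
#'   for where the complication event costs came from.
#' @return An object of class `ats_params`.
#' @seealso [base_case_parameters()], [validate_parameters()]
#' @export
ats_parameters <- function(rates_nonoperative, relative_risks,
                           rates_operative = NULL, episode_costs,
                           complication_costs = c(major = 0, minor = 0),
                           wage, utilities = utility_schedule(),
                           settings = run_settings(),
                           hospitalization_ci = NULL,
                           complication_cost_source = c("user", "calibrated")) {
  complication_cost_source <- match.arg(complication_cost_source)
  rate_source <- if (is.null(rates_operative)) "derived" else "table"
  if (is.null(rates_operative)) {
    rates_operative <- derive_operative_rates(relative_risks, rates_nonoperative)
  }
  p <- structure(list(
    rates_nonoperative = rates_nonoperative,
    rates_operative = rates_operative,
    rate_source = rate_source,
    relative_risks = relative_risks,
    episode_costs = episode_costs,
    hospitalization_ci = hospitalization_ci,
    complication_costs = list(major = unname(complication_costs[["major"]]),
                              minor = unname(complication_costs[["minor"]]),
                              source = complication_cost_source),
    wage = wage,
    utilities = utilities,
    settings = settings
  ), class = "ats_params")
  validate_parameters(p)
}

#' Validate a parameter set
#'
#' Checks every structural invariant of an `ats_params` object: probabilities
#' in range and subunitary in sum, non-negative costs, a zero non-operative
#' hospitalization, utilities in `[0, 1]` and non-decreasing, and internally
#' consistent run settings. When operative rates are flagged as derived, they
#' must equal risk ratio times non-operative rate.
#'
#' @param params An `ats_params` object.
#' @return `params`, invisibly, or an error naming the offending field.
#' @export
validate_parameters <- function(params) {
  if (!inherits(params, "ats_params")) abort("validate_parameters(): not an ats_params object.")
  check_event_rates(params$rates_nonoperative[EVENTS], "rates_nonoperative")
  check_event_rates(params$rates_operative[EVENTS], "rates_operative")
  ec <- params$episode_costs
  if (!setequal(ec$episode, EPISODES)) {
    abort("episode_costs: need exactly one row per episode kind (operative, non_operative, rerupture_surgery).")
  }
  comp <- as.matrix(ec[, c("hospitalization", "surgeon", "physical_therapy", "weeks_missed")])
  if (any(!is.finite(comp)) || any(comp < 0)) {
    abort("episode_costs: all components must be finite and >= 0.")
  }
  if (ec$hospitalization[ec$episode == "non_operative"] != 0) {
    abort("episode_costs: non-operative hospitalization must be 0.")
  }
  cc <- params$complication_costs
  if (!is.finite(cc$major) || !is.finite(cc$minor)) {
    abort("complication_costs: major and minor must be finite.")
  }
  if (params$wage$hourly_wage < 0 || params$wage$hours_per_week < 0) {
    abort("wage: hourly_wage and hours_per_week must be >= 0.")
  }
  u <- params$utilities
  if (any(u$recovery < 0) || any(u$recovery > 1) || is.unsorted(u$recovery)) {
    abort("utilities: recovery schedule must be non-decreasing within [0, 1].")
  }
  s <- params$settings
  if (abs(s$horizon - s$cycle_length * s$n_cycles) > 1e-12) {
    abort("settings: horizon must equal n_cycles * cycle_length.")
  }
  if (identical(params$rate_source, "derived")) {
    expect <- derive_operative_rates(params$relative_risks, params$rates_nonoperative)
    if (max(abs(expect - params$rates_operative[EVENTS])) > 1e-12) {
      abort("rates_operative: flagged as derived but inconsistent with relative_risks x rates_nonoperative.")
    }
  }
  invisible(params)
}

#' @export
print.ats_params <- function(x, ...) {
  cat("<ats_params> Achilles tendon rupture cost-utility inputs\n")
  cat(sprintf("  horizon: %g y in %d cycles of %g y; discount %g/y\n",
              x$settings$horizon, x$settings$n_cycles, x$settings$cycle_length,
              x$settings$discount_rate))
  r <- rbind(operative = x$rates_operative, non_operative = x$rates_nonoperative)
  cat(sprintf("  rates (%s): op %.1f/%.1f/%.1f%%, non-op %.1f/%.1f/%.1f%% (rerupture/major/minor)\n",
              x$rate_source, 100 * r[1, 1], 100 * r[1, 2], 100 * r[1, 3],
              100 * r[2, 1], 100 * r[2, 2], 100 * r[2, 3]))
  for (ep in EPISODES) {
    cat(sprintf("  episode %-17s total $%.2f\n", ep, episode_cost_total(x, ep)))
  }
  cat(sprintf("  complication event costs (%s): major $%.2f, minor $%.2f\n",
              x$complication_costs$source, x$complication_costs$major,
              x$complication_costs$minor))
  cat(sprintf("  utilities: %s; minor x%g, major x%g; non-op ratio %g (%s persistence)\n",
              paste(x$utilities$recovery, collapse = "/"),
              x$utilities$minor_multiplier, x$utilities$major_multiplier,
              x$utilities$nonoperative_ratio, x$utilities$complication_persistence))
  invisible(x)
}

# ---- parameter paths ------------------------------------------------------

# Dotted-path accessors used by sweeps, threshold search and the PSA.
# Supported heads: rates_nonoperative.<event>, rates_operative.<event>,
# relative_risks.<event>.<col>, episode_costs.<episode>.<col>,
# complication_costs.{major,minor}, wage.{hourly_wage,hours_per_week},
# utilities.{nonoperative_ratio,minor_multiplier,major_multiplier},
# utilities.recovery.<i>, settings.<field>.

#' Read a model parameter by dotted path
#'
#' @param params An `ats_params` object.
#' @param path Dotted path, e.g. `"episode_costs.operative.hospitalization"`
#'   or `"wage.hourly_wage"`.
#' @return The addressed numeric value.
#' @export
param_get <- function(params, path) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  head1 <- parts[1]
  if (head1 %in% c("rates_nonoperative", "rates_operative")) {
    return(params[[head1]][[parts[2]]])
  }
  if (head1 == "relative_risks") {
    return(params$relative_risks[[parts[3]]][params$relative_risks$event == parts[2]])
  }
  if (head1 == "episode_costs") {
    return(params$episode_costs[[parts[3]]][params$episode_costs$episode == parts[2]])
  }
  if (head1 == "utilities" && parts[2] == "recovery") {
    return(params$utilities$recovery[as.integer(parts[3])])
  }
  if (head1 %in% c("complication_costs", "wage", "utilities", "settings")) {
    return(params[[head1]][[parts[2]]])
  }
  abort(sprintf("param_get(): unknown parameter path '%s'.", path))
}

#' Set a model parameter by dotted path
#'
#' Returns a modified copy; the parameter set is revalidated, and derived
#' operative rates are recomputed when their inputs change.
#'
#' @inheritParams param_get
#' @param value Replacement numeric value.
#' @param revalidate Check all invariants afterwards (default `TRUE`).
#' @return A modified `ats_params` object.
#' @export
param_set <- function(params, path, value, revalidate = TRUE) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  head1 <- parts[1]
  if (head1 %in% c("rates_nonoperative", "rates_operative")) {
    params[[head1]][[parts[2]]] <- value
    if (head1 == "rates_operative") params$rate_source <- "table"
  } else if (head1 == "relative_risks") {
    params$relative_risks[[parts[3]]][params$relative_risks$event == parts[2]] <- value
  } else if (head1 == "episode_costs") {
    params$episode_costs[[parts[3]]][params$episode_costs$episode == parts[2]] <- value
  } else if (head1 == "utilities" && parts[2] == "recovery") {
    params$utilities$recovery[as.integer(parts[3])] <- value
    params$utilities$full_benefit <- params$utilities$recovery[length(params$utilities$recovery)]
  } else if (head1 %in% c("complication_costs", "wage", "utilities", "settings")) {
    params[[head1]][[parts[2]]] <- value
    if (head1 == "settings" && parts[2] %in% c("cycle_length", "n_cycles")) {
      params$settings$horizon <- params$settings$cycle_length * params$settings$n_cycles
    }
  } else {
    abort(sprintf("param_set(): unknown parameter path '%s'.", path))
  }
  if (identical(params$rate_source, "derived") &&
      head1 %in% c("rates_nonoperative", "relative_risks")) {
    params$rates_operative <- derive_operative_rates(params$relative_risks,
                                                     params$rates_nonoperative)
  }
  if (revalidate) validate_parameters(params) else params
}
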