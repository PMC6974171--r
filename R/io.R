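# Parameter-file dialect: one YAML document mirroring the parameter set
# field-for-field. The bundled base case written by write_parameters() is the
# reference example of the dialect.

#' Write a parameter set to a YAML file
#'
#' @param params An [ats_parameters()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_parameters()]
#' @export
write_parameters <- function(params, path) {
  doc <- list(
    rates_nonoperative = as.list(params$rates_nonoperative[EVENTS]),
    rates_operative = if (identical(params$rate_source, "table"))
      as.list(params$rates_operative[EVENTS]) else NULL,
    relative_risks = purrr::transpose(as.list(params$relative_risks)),
    episode_costs = purrr::transpose(as.list(params$episode_costs)),
    hospitalization_ci = if (!is.null(params$hospitalization_ci))
      as.list(params$hospitalization_ci),
    complication_costs = params$complication_costs,
    wage = params$wage,
    utilities = params$utilities[c("recovery", "minor_multiplier",
                                   "major_multiplier", "nonoperative_ratio",
                                   "complication_persistence")],
    settings = params$settings[c("cycle_length", "n_cycles", "discount_rate",
                                 "wtp_grid", "psa_iterations", "seed")]
  )
  doc <- doc[!vapply(doc, is.null, logical(1))]
  yaml::write_yaml(doc, path, precision = 17)
  invisible(path)
}

#' Read a parameter set from a YAML file
#'
#' Reads a parameter file in the dialect written by [write_parameters()] and
#' validates every invariant. Omitting `rates_operative` derives the
#' operative rates from the relative risks.
#'
#' @param path Path to a YAML parameter file.
#' @return A validated `ats_params` object.
#' @export
read_parameters <- function(path) {
  if (!file.exists(path)) abort(sprintf("read_parameters(): no such file '%s'.", path))
  doc <- yaml::read_yaml(path)
  required <- c("rates_nonoperative", "relative_risks", "episode_costs",
                "wage", "utilities", "settings")
  missing <- setdiff(required, names(doc))
  if (length(missing)) {
    abort(sprintf("read_parameters(): missing required fields: %s.",
                  paste(missing, collapse = ", ")))
  }
  as_rates <- function(x, field) {
    if (!all(EVENTS %in% names(x))) {
      abort(sprintf("read_parameters(): %s must name rerupture, major and minor.", field))
    }
    event_rates(x$rerupture, x$major, x$minor)
  }
  rrl <- purrr::transpose(doc$relative_risks)
  rr <- relative_risks(unlist(rrl$event), unlist(rrl$point),
                       unlist(rrl$ci_low), unlist(rrl$ci_high))
  ecl <- purrr::transpose(doc$episode_costs)
  ec <- purrr::pmap_dfr(
    list(unlist(ecl$episode), unlist(ecl$hospitalization), unlist(ecl$surgeon),
         unlist(ecl$physical_therapy), unlist(ecl$weeks_missed)),
    episode_costs)
  u <- doc$utilities
  s <- doc$settings
  cc <- doc$complication_costs %||% list(major = 0, minor = 0, source = "user")
  ats_parameters(
    rates_nonoperative = as_rates(doc$rates_nonoperative, "rates_nonoperative"),
    relative_risks = rr,
    rates_operative = if (!is.null(doc$rates_operative))
      as_rates(doc$rates_operative, "rates_operative"),
    episode_costs = ec,
    complication_costs = c(major = cc$major, minor = cc$minor),
    wage = wage_model(doc$wage$hourly_wage, doc$wage$hours_per_week %||% 40),
    utilities = utility_schedule(
      recovery = unlist(u$recovery),
      minor_multiplier = u$minor_multiplier,
      major_multiplier = u$major_multiplier,
      nonoperative_ratio = u$nonoperative_ratio %||% 1,
      complication_persistence = u$complication_persistence %||% "horizon"),
    settings = run_settings(
      cycle_length = s$cycle_length, n_cycles = s$n_cycles,
      discount_rate = s$discount_rate %||% 0,
      wtp_grid = unlist(s$wtp_grid),
      psa_iterations = s$psa_iterations %||% 10000,
      seed = s$seed),
    hospitalization_ci = if (!is.null(doc$hospitalization_ci))
      c(low = doc$hospitalization_ci$low, high = doc$hospitalization_ci$high),
    complication_cost_source = cc$source %||% "user"
  )
}
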