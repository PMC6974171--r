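# High-level reporting stages behind the command-line interface. Each stage
# returns its results as R objects and, given an output directory, writes the
# machine-readable artifacts plus a run manifest that records the seed, tool
# version and every assumed default actually used.

#' Build a run manifest
#'
#' @param command Stage name (e.g. `"base-case"`).
#' @param config Path of the parameter file used, or a fixture label.
#' @param seed RNG seed used, if any.
#' @param params The parameter set actually run (its assumed defaults are
#'   echoed).
#' @param extra Named list of stage-specific entries.
#' @return A list suitable for JSON serialisation.
#' @export
run_manifest <- function(command, config, seed = NULL, params = NULL,
                         extra = list()) {
  m <- list(
    command = command,
    config = config,
    seed = seed,
    tool = "tendocea",
    version = as.character(utils::packageVersion("tendocea")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  if (!is.null(params)) {
    m$assumed_defaults <- list(
      rate_source = params$rate_source,
      complication_costs = params$complication_costs,
      hourly_wage = params$wage$hourly_wage,
      complication_persistence = params$utilities$complication_persistence,
      nonoperative_utility_ratio = params$utilities$nonoperative_ratio,
      discount_rate = params$settings$discount_rate
    )
  }
  c(m, extra)
}

write_manifest <- function(manifest, out_dir, name) {
  jsonlite::write_json(manifest, file.path(out_dir, name),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
}

#' Base-case report
#'
#' Runs both strategies, compares them, and optionally writes the summary
#' JSON, both cohort traces and a manifest.
#'
#' @param params An [ats_parameters()] object.
#' @param wtp_grid Willingness-to-pay grid (default from run settings).
#' @param out_dir Output directory (`NULL` to skip writing).
#' @param config Label recorded in the manifest.
#' @return A list with `comparison` (an `ats_comparison`), `outcomes` and the
#'   `manifest`.
#' @export
report_base_case <- function(params, wtp_grid = NULL, out_dir = NULL,
                             config = "<in-code>") {
  out <- run_strategies(params)
  cmp <- compare_strategies(out$non_operative, out$operative, wtp_grid)
  manifest <- run_manifest("base-case", config, params = params)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    export_comparison(cmp, file.path(out_dir, "base_case.json"))
    export_trace(out$non_operative, file.path(out_dir, "trace_non_operative.csv"))
    export_trace(out$operative, file.path(out_dir, "trace_operative.csv"))
    write_manifest(manifest, out_dir, "base_case_manifest.json")
  }
  list(comparison = cmp, outcomes = out, manifest = manifest)
}

#' Calibration report
#'
#' Calibrates the complication event costs to target strategy totals and
#' records the solved values and the achieved residual.
#'
#' @inheritParams report_base_case
#' @param target_operative,target_nonoperative Target totals (USD); default
#'   to the published base-case totals.
#' @param allow_negative Passed to [calibrate_complication_costs()]; the
#'   published targets require `TRUE` (see that function's documentation).
#' @return A list with the calibrated `params`, the `calibration` record and
#'   the `manifest`.
#' @export
report_calibration <- function(params,
                               target_operative = BASE_CASE_TOTALS[["operative"]],
                               target_nonoperative = BASE_CASE_TOTALS[["non_operative"]],
                               allow_negative = TRUE, out_dir = NULL,
                               config = "<in-code>") {
  params <- calibrate_complication_costs(params, target_operative,
                                         target_nonoperative, allow_negative)
  cal <- attr(params, "calibration")
  manifest <- run_manifest("calibrate", config, params = params, extra = list(
    calibration = list(major = cal$major, minor = cal$minor,
                       residual_operative = cal$residual[["operative"]],
                       residual_nonoperative = cal$residual[["non_operative"]],
                       targets = as.list(cal$targets))))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_manifest(manifest, out_dir, "calibration_manifest.json")
    write_parameters(params, file.path(out_dir, "calibrated_parameters.yaml"))
  }
  list(params = params, calibration = cal, manifest = manifest)
}

# The default one-way ranges swept by the deterministic stage: the
# non-operative utility ratio within 5% of parity, operative hospitalization
# cost halved/doubled, the hourly wage halved/doubled, and each operative
# event rate over the range implied by its risk-ratio 95% CI (CI bound times
# the non-operative rate), clipped so the arm's event mass stays below 0.95.
default_dsa_specs <- function(params) {
  ec <- function(ep, col) params$episode_costs[[col]][params$episode_costs$episode == ep]
  rrr <- function(ev, col) params$relative_risks[[col]][params$relative_risks$event == ev]
  rate_bounds <- function(ev) {
    q <- params$rates_nonoperative[[ev]]
    others <- sum(params$rates_operative[EVENTS]) - params$rates_operative[[ev]]
    c(low = rrr(ev, "ci_low") * q,
      high = min(rrr(ev, "ci_high") * q, 0.95 - others))
  }
  rb <- lapply(setNames(EVENTS, EVENTS), rate_bounds)
  tibble(
    parameter = c("utilities.nonoperative_ratio",
                  "episode_costs.operative.hospitalization",
                  "wage.hourly_wage",
                  "rates_operative.rerupture",
                  "rates_operative.major",
                  "rates_operative.minor"),
    low = c(0.95, ec("operative", "hospitalization") / 2,
            params$wage$hourly_wage / 2,
            rb$rerupture[["low"]], rb$major[["low"]], rb$minor[["low"]]),
    high = c(1.05, ec("operative", "hospitalization") * 2,
             params$wage$hourly_wage * 2,
             rb$rerupture[["high"]], rb$major[["high"]], rb$minor[["high"]])
  )
}

#' Deterministic sensitivity report
#'
#' Runs the threshold searches for the headline drivers (operative
#' hospitalization cost and hourly wage under cost parity; the proportional
#' non-operative utility ratio under an NMB flip) and, optionally, a tornado
#' ranking over default or supplied ranges.
#'
#' @inheritParams report_base_case
#' @param wtp Willingness-to-pay for the NMB-based criteria.
#' @param tornado_specs Data frame (`parameter`, `low`, `high`) for the
#'   tornado; `NULL` for the package defaults.
#' @return A list with `thresholds` (tibble), `tornado` (tibble) and the
#'   `manifest`.
#' @export
report_dsa <- function(params, wtp = NULL, tornado_specs = NULL,
                       out_dir = NULL, config = "<in-code>") {
  wtp <- wtp %||% min(params$settings$wtp_grid)
  hosp <- param_get(params, "episode_costs.operative.hospitalization")
  thresholds <- dplyr::bind_rows(
    find_threshold(params, "episode_costs.operative.hospitalization",
                   bounds = c(0, hosp), wtp = wtp, criterion = "cost_parity"),
    find_threshold(params, "wage.hourly_wage",
                   bounds = c(params$wage$hourly_wage, 4 * params$wage$hourly_wage),
                   wtp = wtp, criterion = "cost_parity"),
    find_threshold(params, "utilities.nonoperative_ratio",
                   bounds = c(0.9, 1), wtp = wtp, criterion = "nmb_flip")
  )
  torn <- tornado(params, tornado_specs %||% default_dsa_specs(params), wtp)
  manifest <- run_manifest("dsa", config, params = params,
                           extra = list(wtp = wtp))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(thresholds, file.path(out_dir, "thresholds.csv"))
    readr::write_csv(torn, file.path(out_dir, "tornado.csv"))
    write_manifest(manifest, out_dir, "dsa_manifest.json")
  }
  list(thresholds = thresholds, tornado = torn, manifest = manifest)
}

#' Probabilistic sensitivity report
#'
#' Runs the Monte Carlo analysis and writes the per-draw table, the
#' acceptability curve and a manifest embedding the seed and the full
#' distribution specification actually sampled.
#'
#' @inheritParams report_base_case
#' @param n Number of draws (default from run settings).
#' @param seed RNG seed (required).
#' @param spec Distribution table (default [default_psa_spec()]).
#' @return A list with `psa` (an `ats_psa`) and the `manifest`.
#' @export
report_psa <- function(params, n = NULL, seed, spec = default_psa_spec(params),
                       out_dir = NULL, config = "<in-code>") {
  psa <- run_psa(params, n = n, seed = seed, spec = spec)
  spec_echo <- dplyr::mutate(spec, paths = vapply(spec$paths, paste,
                                                  character(1), collapse = ";"))
  manifest <- run_manifest("psa", config, seed = seed, params = params,
                           extra = list(
                             iterations = psa$n,
                             acceptability = psa$acceptability,
                             distributions = spec_echo))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    export_psa(psa, file.path(out_dir, "psa_draws.csv"),
               file.path(out_dir, "ceac.csv"))
    write_manifest(manifest, out_dir, "psa_manifest.json")
  }
  list(psa = psa, manifest = manifest)
}

#' Dump a named fixture as a parameter file
#'
#' @param name One of `"base_case"`, `"base_case_uncalibrated"`,
#'   `"zero_events"`, `"equal_arms"`, `"certain_rerupture"`.
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
dump_fixture <- function(name, path) {
  params <- switch(name,
    base_case = base_case_parameters(calibrated = TRUE),
    base_case_uncalibrated = base_case_parameters(calibrated = FALSE),
    zero_events = degenerate_scenarios()$zero_events$params,
    equal_arms = degenerate_scenarios()$equal_arms$params,
    certain_rerupture = degenerate_scenarios()$certain_rerupture$params,
    abort(sprintf("dump_fixture(): unknown fixture '%s'.", name)))
  write_parameters(params, path)
}
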