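# Probabilistic sensitivity analysis: distribution specifications, parameter
# sampling, the Monte Carlo loop and cost-effectiveness acceptability curves.
#
# Distribution families follow standard practice for decision models: beta
# for probabilities, lognormal for relative risks, gamma for costs,
# (truncated) normal for utilities. Spread parameters are taken from printed
# 95% CIs where available (relative risks, operative hospitalization cost:
# SE = CI width / 3.92); every other spread is an explicit package default —
# SE = 10% of the mean for costs, 20% of the mean for probabilities, SD 0.05
# for utilities — echoed in the specification tibble and overridable.

#' Default PSA distribution specification
#'
#' Builds the distribution table the probabilistic sensitivity analysis
#' samples from, one row per uncertain parameter, in the fixed order the
#' random-number stream is consumed (row order is part of the reproducibility
#' contract). The `paths` list-column names every parameter-set location a
#' draw is written to, so quantities that are a single fee in reality (the
#' surgeon fee shared by primary and re-rupture surgery, the
#' physical-therapy course shared by all episodes) are drawn once. The
#' relative utility of the non-operative arm (`utilities.nonoperative_ratio`)
#' is sampled alongside the schedule itself: the base case assumes utility
#' parity between arms, and the sampled ratio (mean 1, SD `utility_sd`)
#' expresses the uncertainty in that assumption.
#'
#' @param params An [ats_parameters()] object.
#' @param cost_se_frac Default SE as a fraction of the mean for costs without
#'   a printed CI (default 0.10).
#' @param prob_se_frac Default SE as a fraction of the mean for event
#'   probabilities (default 0.20).
#' @param utility_sd Default SD for utilities and decrement multipliers
#'   (default 0.05).
#' @return A tibble with columns `parameter`, `family`, `mean`, `se`,
#'   `ci_low`, `ci_high` (risk ratios only), `lower`, `upper` (truncation
#'   bounds) and `paths` (list of dotted parameter paths).
#' @export
default_psa_spec <- function(params, cost_se_frac = 0.10, prob_se_frac = 0.20,
                             utility_sd = 0.05) {
  ec <- function(ep, col) params$episode_costs[[col]][params$episode_costs$episode == ep]
  rrrow <- function(ev) params$relative_risks[params$relative_risks$event == ev, ]
  hosp_ci <- params$hospitalization_ci
  hosp_se <- if (!is.null(hosp_ci)) (hosp_ci[["high"]] - hosp_ci[["low"]]) / 3.92
             else cost_se_frac * ec("operative", "hospitalization")
  row <- function(parameter, family, mean, se, ci_low = NA_real_,
                  ci_high = NA_real_, lower = -Inf, upper = Inf,
                  paths = list(parameter)) {
    tibble(parameter = parameter, family = family, mean = mean, se = se,
           ci_low = ci_low, ci_high = ci_high, lower = lower, upper = upper,
           paths = list(unlist(paths)))
  }
  dplyr::bind_rows(
    row("rates_nonoperative.rerupture", "beta",
        params$rates_nonoperative[["rerupture"]],
        prob_se_frac * params$rates_nonoperative[["rerupture"]]),
    row("rates_nonoperative.major", "beta",
        params$rates_nonoperative[["major"]],
        prob_se_frac * params$rates_nonoperative[["major"]]),
    row("rates_nonoperative.minor", "beta",
        params$rates_nonoperative[["minor"]],
        prob_se_frac * params$rates_nonoperative[["minor"]]),
    row("relative_risks.rerupture.point", "lognormal", rrrow("rerupture")$point,
        NA_real_, rrrow("rerupture")$ci_low, rrrow("rerupture")$ci_high),
    row("relative_risks.major.point", "lognormal", rrrow("major")$point,
        NA_real_, rrrow("major")$ci_low, rrrow("major")$ci_high),
    row("relative_risks.minor.point", "lognormal", rrrow("minor")$point,
        NA_real_, rrrow("minor")$ci_low, rrrow("minor")$ci_high),
    row("episode_costs.operative.hospitalization", "gamma",
        ec("operative", "hospitalization"), hosp_se),
    row("episode_costs.rerupture_surgery.hospitalization", "gamma",
        ec("rerupture_surgery", "hospitalization"),
        cost_se_frac * ec("rerupture_surgery", "hospitalization")),
    row("surgeon_fee_operative", "gamma", ec("operative", "surgeon"),
        cost_se_frac * ec("operative", "surgeon"),
        paths = list(c("episode_costs.operative.surgeon",
                       "episode_costs.rerupture_surgery.surgeon"))),
    row("surgeon_fee_nonoperative", "gamma", ec("non_operative", "surgeon"),
        cost_se_frac * ec("non_operative", "surgeon"),
        paths = list("episode_costs.non_operative.surgeon")),
    row("physical_therapy_fee", "gamma", ec("operative", "physical_therapy"),
        cost_se_frac * ec("operative", "physical_therapy"),
        paths = list(c("episode_costs.operative.physical_therapy",
                       "episode_costs.non_operative.physical_therapy",
                       "episode_costs.rerupture_surgery.physical_therapy"))),
    row("wage.hourly_wage", "gamma", params$wage$hourly_wage,
        cost_se_frac * params$wage$hourly_wage),
    row("complication_costs.major", "gamma", params$complication_costs$major,
        cost_se_frac * abs(params$complication_costs$major)),
    row("complication_costs.minor", "gamma", params$complication_costs$minor,
        cost_se_frac * abs(params$complication_costs$minor)),
    row("utilities.recovery.1", "normal_truncated", params$utilities$recovery[1],
        utility_sd, lower = 0, upper = 1),
    row("utilities.recovery.2", "normal_truncated", params$utilities$recovery[2],
        utility_sd, lower = 0, upper = 1),
    row("utilities.recovery.3", "normal_truncated", params$utilities$recovery[3],
        utility_sd, lower = 0, upper = 1),
    row("utilities.minor_multiplier", "normal_truncated",
        params$utilities$minor_multiplier, utility_sd, lower = 1e-12, upper = 1),
    row("utilities.major_multiplier", "normal_truncated",
        params$utilities$major_multiplier, utility_sd, lower = 1e-12, upper = 1),
    # relative utility of the non-operative arm: the base case assumes parity
    # between arms, but that equality is itself the model's least certain and
    # most influential input, so the PSA samples it with the utility SD.
    # Truncated above so non-operative utilities stay within [0, 1].
    row("utilities.nonoperative_ratio", "normal_truncated",
        params$utilities$nonoperative_ratio, utility_sd,
        lower = 0, upper = 1 / params$utilities$full_benefit)
  )
}

# Draw n values from one spec row using the current RNG state.
# Beta and gamma parameters come from method-of-moments on (mean, SE);
# lognormal uses log-mean ln(point) and log-SD (ln(ci_high) - ln(ci_low))/3.92.
# A gamma row with a negative mean is sampled on its magnitude with the sign
# restored (needed for a calibrated negative cost offset).
draw_psa_row <- function(spec_row, n) {
  m <- spec_row$mean
  s <- spec_row$se
  x <- switch(spec_row$family,
    beta = {
      if (s == 0) rep(m, n) else {
        if (s^2 >= m * (1 - m)) {
          abort(sprintf("PSA spec '%s': SE %.4g too large for a beta with mean %.4g.",
                        spec_row$parameter, s, m))
        }
        nu <- m * (1 - m) / s^2 - 1
        rbeta(n, m * nu, (1 - m) * nu)
      }
    },
    gamma = {
      if (s == 0 || m == 0) rep(m, n) else {
        sgn <- sign(m); ma <- abs(m)
        sgn * rgamma(n, shape = (ma / s)^2, rate = ma / s^2)
      }
    },
    lognormal = {
      sdlog <- (log(spec_row$ci_high) - log(spec_row$ci_low)) / 3.92
      if (sdlog == 0) rep(m, n) else rlnorm(n, meanlog = log(m), sdlog = sdlog)
    },
    normal_truncated = {
      if (s == 0) rep(m, n) else pmin(pmax(rnorm(n, m, s), spec_row$lower),
                                      spec_row$upper)
    },
    abort(sprintf("PSA spec '%s': unknown family '%s'.",
                  spec_row$parameter, spec_row$family)))
  pmin(pmax(x, spec_row$lower), spec_row$upper)
}

# n x n_spec matrix of draws, consumed column-by-column in spec row order
draw_psa_matrix <- function(spec, n) {
  cols <- lapply(seq_len(nrow(spec)), function(i) draw_psa_row(spec[i, ], n))
  m <- do.call(cbind, cols)
  colnames(m) <- spec$parameter
  m
}

# Write one row of draws into a parameter set, propagating the event-rate
# uncertainty into the operative arm: each operative rate is scaled by the
# sampled-to-base ratio of its risk ratio and of its non-operative rate, so
# that a zero-variance draw reproduces the base case exactly while RR and
# rate uncertainty propagate multiplicatively. Rates are clipped to [0, 1]
# and rescaled if an arm's event mass reaches 1.
apply_psa_draw <- function(params, spec, draw) {
  base <- params
  for (i in seq_len(nrow(spec))) {
    for (path in spec$paths[[i]]) {
      params <- param_set(params, path, draw[[spec$parameter[i]]], revalidate = FALSE)
    }
  }
  scale_or_1 <- function(new, old) ifelse(old > 0, new / old, 1)
  rr_scale <- scale_or_1(params$relative_risks$point, base$relative_risks$point)
  names(rr_scale) <- params$relative_risks$event
  q_scale <- scale_or_1(params$rates_nonoperative[EVENTS],
                        base$rates_nonoperative[EVENTS])
  op <- base$rates_operative[EVENTS] * rr_scale[EVENTS] * q_scale
  params$rates_nonoperative <- clip_rates(params$rates_nonoperative[EVENTS])
  params$rates_operative <- clip_rates(op)
  params$rate_source <- "table"
  # recovery utilities are sampled independently; restore monotonicity by
  # sorting, which preserves the marginals of the order statistics
  params$utilities$recovery <- sort(params$utilities$recovery)
  params$utilities$full_benefit <- params$utilities$recovery[length(params$utilities$recovery)]
  params
}

clip_rates <- function(r) {
  r <- pmin(pmax(r, 0), 1)
  if (sum(r) >= 1) r <- r * 0.999999 / sum(r)
  r
}

#' Sample one parameter set from the PSA distributions
#'
#' Draws every uncertain parameter once (consuming the RNG stream in spec row
#' order) and returns a complete, valid parameter set. With all spreads at
#' zero the base case is returned exactly.
#'
#' @param params Base [ats_parameters()].
#' @param spec Distribution table from [default_psa_spec()].
#' @return A valid `ats_params` object.
#' @export
sample_parameter_set <- function(params, spec = default_psa_spec(params)) {
  draw <- draw_psa_matrix(spec, 1)[1, ]
  validate_parameters(apply_psa_draw(params, spec, draw))
}

#' Probabilistic sensitivity analysis
#'
#' Runs `n` Monte Carlo iterations: each draws all uncertain parameters
#' simultaneously from `spec`, runs both strategies through the cohort
#' engine, and records incremental cost and QALYs (operative minus
#' non-operative). Acceptability at each willingness-to-pay value is the
#' fraction of draws in which each strategy has the highest net monetary
#' benefit (ties go to non-operative, the reference).
#'
#' @param params Base [ats_parameters()].
#' @param n Number of draws (default: `psa_iterations` from the run
#'   settings).
#' @param seed Integer RNG seed; required for reproducibility (same seed,
#'   same spec: bitwise-identical draws).
#' @param spec Distribution table from [default_psa_spec()].
#' @param wtp_grid Willingness-to-pay grid (default from run settings).
#' @return An object of class `ats_psa`: list with `draws` (tibble: `draw`,
#'   per-strategy costs/QALYs, `delta_cost`, `delta_qalys`), `acceptability`
#'   (tibble: `wtp`, `fraction_nonoperative`, `fraction_operative`), `seed`,
#'   `n` and the echoed `spec`.
#' @examples
#' p <- base_case_parameters()
#' psa <- run_psa(p, n = 200, seed = 42)
#' psa$acceptability
#' @export
run_psa <- function(params, n = NULL, seed, spec = default_psa_spec(params),
                    wtp_grid = NULL) {
  validate_parameters(params)
  n <- n %||% params$settings$psa_iterations
  if (n < 1) abort("run_psa(): need n >= 1.")
  wtp_grid <- wtp_grid %||% params$settings$wtp_grid
  set.seed(seed)
  draws <- draw_psa_matrix(spec, n)
  res <- matrix(NA_real_, nrow = n, ncol = 4,
                dimnames = list(NULL, c("cost_nonoperative", "qalys_nonoperative",
                                        "cost_operative", "qalys_operative")))
  for (i in seq_len(n)) {
    p_i <- apply_psa_draw(params, spec, draws[i, ])
    rn <- do.call(engine_run, engine_args(p_i, "non_operative"))
    ro <- do.call(engine_run, engine_args(p_i, "operative"))
    res[i, ] <- c(rn$total_cost, rn$total_qalys, ro$total_cost, ro$total_qalys)
  }
  draws_tbl <- as_tibble(res)
  draws_tbl <- dplyr::mutate(draws_tbl,
                             draw = dplyr::row_number(),
                             delta_cost = .data$cost_operative - .data$cost_nonoperative,
                             delta_qalys = .data$qalys_operative - .data$qalys_nonoperative,
                             .before = 1)
  acc <- psa_acceptability(draws_tbl, wtp_grid)
  structure(list(draws = draws_tbl, acceptability = acc, seed = seed, n = n,
                 wtp_grid = wtp_grid, spec = spec, params = params),
            class = "ats_psa")
}

psa_acceptability <- function(draws_tbl, wtp_grid) {
  purrr::map_dfr(wtp_grid, function(l) {
    op <- mean(l * draws_tbl$delta_qalys - draws_tbl$delta_cost > NMB_TIE_TOL)
    tibble(wtp = l, fraction_nonoperative = 1 - op, fraction_operative = op)
  })
}

#' Cost-effectiveness acceptability curve
#'
#' Fraction of PSA draws in which each strategy is preferred (highest net
#' monetary benefit), over a willingness-to-pay grid.
#'
#' @param psa An `ats_psa` from [run_psa()].
#' @param wtp_grid Willingness-to-pay grid; defaults to 0 to $150,000/QALY in
#'   $2,500 steps.
#' @return A tibble: `wtp`, `fraction_nonoperative`, `fraction_operative`.
#' @export
ceac <- function(psa, wtp_grid = seq(0, 150000, by = 2500)) {
  psa_acceptability(psa$draws, wtp_grid)
}

#' @export
print.ats_psa <- function(x, ...) {
  cat(sprintf("<ats_psa> %d Monte Carlo draws (seed %s)\n", x$n, format(x$seed)))
  for (i in seq_len(nrow(x$acceptability))) {
    cat(sprintf("  at $%s/QALY: non-operative preferred in %.1f%% of draws\n",
                format(x$acceptability$wtp[i], big.mark = ","),
                100 * x$acceptability$fraction_nonoperative[i]))
  }
  invisible(x)
}

#' @rdname run_psa
#' @param x An `ats_psa`.
#' @param ... Unused.
#' @export
tidy.ats_psa <- function(x, ...) x$draws

#' @rdname run_psa
#' @export
glance.ats_psa <- function(x, ...) {
  tidyr::pivot_wider(x$acceptability, names_from = "wtp",
                     values_from = c("fraction_nonoperative", "fraction_operative")) |>
    dplyr::mutate(n = x$n, seed = x$seed, .before = 1)
}

#' Export PSA draws and the acceptability curve
#'
#' @param psa An `ats_psa`.
#' @param draws_path,ceac_path Output CSV paths (either may be `NULL` to
#'   skip).
#' @param wtp_grid Grid for the exported CEAC.
#' @return Invisibly, the written paths.
#' @export
export_psa <- function(psa, draws_path = NULL, ceac_path = NULL,
                       wtp_grid = seq(0, 150000, by = 2500)) {
  if (!is.null(draws_path)) {
    wide <- psa$draws
    for (l in psa$wtp_grid) {
      wide[[paste0("preferred_at_", format(l, scientific = FALSE))]] <-
        ifelse(l * psa$draws$delta_qalys - psa$draws$delta_cost > NMB_TIE_TOL,
               "operative", "non_operative")
    }
    readr::write_csv(wide, draws_path)
  }
  if (!is.null(ceac_path)) readr::write_csv(ceac(psa, wtp_grid), ceac_path)
  invisible(c(draws = draws_path, ceac = ceac_path))
}
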