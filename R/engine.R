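# Markov cohort engine.
#
# Expanded state space: the cohort is tracked by pathway x cycles-since-last-
# treatment. "recovering" is the single pre-resolution cycle that follows any
# treatment (primary or re-rupture surgery); at its end the episode lottery
# splits the mass into full benefit, minor complication, major complication
# or re-rupture. Re-ruptured mass undergoes surgery at the start of the next
# cycle: the re-rupture episode cost is charged, the recovery utility clock
# resets, and the mass re-enters the lottery one cycle later with operative
# probabilities. Complication pathways persist to the horizon by default.
# The lottery at the end of the final cycle is not drawn: its outcomes would
# fall entirely outside the horizon.

PATHWAYS <- c("recovering", "full_benefit", "minor_complication", "major_complication")

#' Episode resolution distribution
#'
#' The one-cycle lottery applied to a freshly treated cohort: probability of
#' full benefit is the complement of the three event probabilities.
#'
#' @param rates [event_rates()] of the treating strategy.
#' @return Named numeric vector `(full_benefit, minor, major, rerupture)`
#'   summing to 1 exactly.
#' @examples
#' resolve_episode(event_rates(0.038, 0.055, 0.154))
#' @export
resolve_episode <- function(rates) {
  check_event_rates(rates[EVENTS], "resolve_episode()")
  c(full_benefit = 1 - sum(rates[EVENTS]),
    minor = unname(rates[["minor"]]),
    major = unname(rates[["major"]]),
    rerupture = unname(rates[["rerupture"]]))
}

# Fast scalar core shared by run_cohort() and the PSA. Occupancy is a
# 4 x n_cycles matrix (pathway x cycles-since-last-treatment); recovering mass
# lives in column 1 only. Returns totals and, optionally, per-cycle snapshots.
engine_run <- function(rates_first, rates_followon,
                       cost_initial, cost_rerupture,
                       minor_cost, major_cost,
                       sched, mult_minor, mult_major, utility_ratio,
                       n_cycles, cycle_length, discount_rate = 0,
                       persistence = "horizon", keep_trace = FALSE) {
  L <- length(sched)
  u_c <- sched[pmin(seq_len(n_cycles), L)]          # utility by clock position
  occ <- matrix(0, nrow = 4, ncol = n_cycles)
  occ[1, 1] <- 1
  cost <- qaly <- numeric(n_cycles)
  cost[1] <- cost_initial
  disc <- (1 + discount_rate)^(-(seq_len(n_cycles) - 1) * cycle_length)
  snapshots <- if (keep_trace) vector("list", n_cycles) else NULL

  for (t in seq_len(n_cycles)) {
    if (keep_trace) snapshots[[t]] <- occ
    rowsum_t <- sum(occ)
    if (abs(rowsum_t - 1) > 1e-9) {
      abort(sprintf("cohort occupancy at cycle %d sums to %.12f, not 1.", t, rowsum_t))
    }
    qaly[t] <- cycle_length * utility_ratio *
      (occ[1, 1] * u_c[1] +
         sum(occ[2, ] * u_c) +
         mult_minor * sum(occ[3, ] * u_c) +
         mult_major * sum(occ[4, ] * u_c))
    if (t == n_cycles) break

    r <- if (t == 1) rates_first else rates_followon
    rec <- occ[1, 1]
    nxt <- matrix(0, nrow = 4, ncol = n_cycles)
    nxt[2, 2:n_cycles] <- occ[2, 1:(n_cycles - 1)]
    if (persistence == "horizon") {
      nxt[3, 2:n_cycles] <- occ[3, 1:(n_cycles - 1)]
      nxt[4, 2:n_cycles] <- occ[4, 1:(n_cycles - 1)]
    } else {  # single_cycle: decrement applies in the entry cycle only
      nxt[2, 2:n_cycles] <- nxt[2, 2:n_cycles] +
        occ[3, 1:(n_cycles - 1)] + occ[4, 1:(n_cycles - 1)]
    }
    nxt[2, 2] <- nxt[2, 2] + rec * (1 - sum(r))
    nxt[3, 2] <- nxt[3, 2] + rec * r[["minor"]]
    nxt[4, 2] <- nxt[4, 2] + rec * r[["major"]]
    nxt[1, 1] <- rec * r[["rerupture"]]
    # complication event costs at occurrence; re-rupture surgery billed in the
    # cycle the surgery happens
    cost[t] <- cost[t] + rec * (r[["minor"]] * minor_cost + r[["major"]] * major_cost)
    cost[t + 1] <- cost[t + 1] + rec * r[["rerupture"]] * cost_rerupture
    occ <- nxt
  }

  list(total_cost = sum(cost * disc), total_qalys = sum(qaly * disc),
       cycle_cost = cost, cycle_qalys = qaly, snapshots = snapshots)
}

# Pull the scalar inputs engine_run() needs for one strategy out of a
# parameter set. Exposed internally so the PSA can bypass object overhead.
engine_args <- function(params, strategy) {
  strategy <- match.arg(strategy, STRATEGIES)
  first <- if (strategy == "operative") params$rates_operative else params$rates_nonoperative
  initial_episode <- if (strategy == "operative") "operative" else "non_operative"
  u <- params$utilities
  list(
    rates_first = first[EVENTS],
    rates_followon = params$rates_operative[EVENTS],  # re-rupture is always surgical
    cost_initial = episode_cost_total(params, initial_episode),
    cost_rerupture = episode_cost_total(params, "rerupture_surgery"),
    minor_cost = params$complication_costs$minor,
    major_cost = params$complication_costs$major,
    sched = u$recovery,
    mult_minor = u$minor_multiplier,
    mult_major = u$major_multiplier,
    utility_ratio = if (strategy == "non_operative") u$nonoperative_ratio else 1,
    n_cycles = params$settings$n_cycles,
    cycle_length = params$settings$cycle_length,
    discount_rate = params$settings$discount_rate,
    persistence = u$complication_persistence
  )
}

#' Run the cohort model for one strategy
#'
#' Simulates the full cohort through the expanded health-state space over the
#' model horizon, accruing expected costs (initial episode, re-rupture
#' surgeries, complication event costs) and quality-adjusted life years
#' (occupancy times scheduled utility times cycle length).
#'
#' @param params An [ats_parameters()] object.
#' @param strategy `"operative"` or `"non_operative"`.
#' @param keep_trace Attach the per-cycle occupancy trace (default `TRUE`;
#'   the probabilistic sensitivity analysis drops it for speed).
#' @return An object of class `ats_outcome` with elements `strategy`,
#'   `total_cost`, `total_qalys` and `trace` (a tibble: `cycle`, `state`,
#'   `cycles_since_treatment`, `occupancy`, `cycle_cost`, `cycle_qalys`;
#'   cycle 0 is the initial distribution).
#' @examples
#' p <- base_case_parameters(calibrated = FALSE)
#' run_cohort(p, "non_operative")
#' @export
run_cohort <- function(params, strategy = c("non_operative", "operative"),
                       keep_trace = TRUE) {
  strategy <- match.arg(strategy)
  validate_parameters(params)
  a <- engine_args(params, strategy)
  res <- do.call(engine_run, c(a, list(keep_trace = keep_trace)))
  trace <- NULL
  if (keep_trace) {
    n <- a$n_cycles
    state_idx <- cbind(pathway = c(1L, rep(2:4, each = n - 1L)),
                       clock = c(1L, rep(2:n, times = 3L)))
    per_cycle <- function(cycle, occm) {
      tibble(cycle = cycle,
             state = PATHWAYS[state_idx[, "pathway"]],
             cycles_since_treatment = state_idx[, "clock"],
             occupancy = occm[state_idx])
    }
    rows <- c(list(per_cycle(0L, res$snapshots[[1]])),
              purrr::imap(res$snapshots, function(m, t) per_cycle(as.integer(t), m)))
    trace <- dplyr::bind_rows(rows)
    accr <- tibble(cycle = c(0L, seq_len(n)),
                   cycle_cost = c(0, res$cycle_cost),
                   cycle_qalys = c(0, res$cycle_qalys))
    trace <- dplyr::left_join(trace, accr, by = "cycle")
  }
  structure(list(strategy = strategy, total_cost = res$total_cost,
                 total_qalys = res$total_qalys, trace = trace,
                 params = params),
            class = "ats_outcome")
}

#' Run both strategies
#'
#' @inheritParams run_cohort
#' @return A named list with elements `non_operative` and `operative`, each
#'   an `ats_outcome`.
#' @export
run_strategies <- function(params, keep_trace = TRUE) {
  setNames(lapply(STRATEGIES, function(s) run_cohort(params, s, keep_trace)),
           STRATEGIES)
}

#' @export
print.ats_outcome <- function(x, ...) {
  cat(sprintf("<ats_outcome> %s: total cost $%.2f, %.4f QALYs over %g y\n",
              x$strategy, x$total_cost, x$total_qalys, x$params$settings$horizon))
  invisible(x)
}

#' @rdname run_cohort
#' @param x An `ats_outcome`.
#' @param ... Unused.
#' @export
tidy.ats_outcome <- function(x, ...) {
  x$trace %||% abort("tidy.ats_outcome(): outcome was run with keep_trace = FALSE.")
}

#' @rdname run_cohort
#' @export
glance.ats_outcome <- function(x, ...) {
  tibble(strategy = x$strategy, total_cost = x$total_cost,
         total_qalys = x$total_qalys,
         horizon_years = x$params$settings$horizon,
         n_cycles = x$params$settings$n_cycles)
}

#' Expected mass of the cohort ever experiencing re-rupture
#'
#' Diagnostic: sums, over treatment generations within the horizon, the
#' probability mass undergoing re-rupture surgery. With follow-on operative
#' re-rupture probability `p` and first-episode probability `q` this is the
#' truncated geometric series `q * (1 + p + p^2 + ...)`.
#'
#' @inheritParams run_cohort
#' @return Expected fraction of the cohort undergoing at least the indexed
#'   re-rupture surgery, summed over generations (counts multiplicity).
#' @export
expected_rerupture_mass <- function(params, strategy = c("non_operative", "operative")) {
  strategy <- match.arg(strategy)
  a <- engine_args(params, strategy)
  rec <- 1
  total <- 0
  for (t in seq_len(a$n_cycles - 1L)) {
    r <- if (t == 1) a$rates_first else a$rates_followon
    total <- total + rec * r[["rerupture"]]
    rec <- rec * r[["rerupture"]]
  }
  total
}

#' Export a cohort trace to CSV
#'
#' Writes the tidy per-cycle trace (one row per cycle per state) of an
#' outcome to a delimited file.
#'
#' @param outcome An `ats_outcome` run with `keep_trace = TRUE`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
export_trace <- function(outcome, path) {
  readr::write_csv(tidy(outcome), path)
  invisible(path)
}
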