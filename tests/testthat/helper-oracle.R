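# Independent brute-force oracle: enumerates every pathway branch of the
# cohort (each re-rupture starts a new treatment generation; full-benefit and
# complication branches run deterministically to the horizon) and sums
# probability-weighted costs and QALYs. Shares no code with the matrix
# engine. Valid for undiscounted settings.
oracle_totals <- function(params, strategy) {
  s <- params$settings
  n <- s$n_cycles
  cl <- s$cycle_length
  u <- params$utilities
  sched <- u$recovery
  L <- length(sched)
  ratio <- if (strategy == "non_operative") u$nonoperative_ratio else 1
  ucyc <- function(cst) sched[min(cst, L)]
  ep_init <- episode_cost_total(params,
                                if (strategy == "operative") "operative" else "non_operative")
  ep_rer <- episode_cost_total(params, "rerupture_surgery")
  mN <- params$complication_costs$minor
  mJ <- params$complication_costs$major
  r_first <- if (strategy == "operative") params$rates_operative else params$rates_nonoperative
  r_follow <- params$rates_operative

  total <- c(cost = 0, qalys = 0)
  recurse <- function(t_treat, prob, cost_acc, qaly_acc, rates) {
    q <- qaly_acc + ucyc(1) * ratio * cl            # treatment cycle, clock = 1
    if (t_treat == n) {
      total <<- total + prob * c(cost_acc, q)
      return(invisible())
    }
    pr <- resolve_episode(rates)
    for (o in c("full_benefit", "minor", "major")) {
      mult <- switch(o, full_benefit = 1, minor = u$minor_multiplier,
                     major = u$major_multiplier)
      qo <- q
      for (t in seq(t_treat + 1, n)) {
        cst <- t - t_treat + 1
        m_t <- if (o == "full_benefit") 1
               else if (u$complication_persistence == "horizon" || cst == 2) mult
               else 1
        qo <- qo + ucyc(cst) * m_t * ratio * cl
      }
      co <- cost_acc + switch(o, minor = mN, major = mJ, full_benefit = 0)
      total <<- total + prob * pr[[o]] * c(co, qo)
    }
    recurse(t_treat + 1, prob * pr[["rerupture"]], cost_acc + ep_rer, q, r_follow)
  }
  recurse(1, 1, ep_init, 0, r_first)
  total
}

# closed-form QALY total when no events ever occur
zero_event_qalys <- function(params) {
  s <- params$settings
  u <- params$utilities$recovery
  sum(u[pmin(seq_len(s$n_cycles), length(u))]) * s$cycle_length
}

# agreement to 1e-9 relative to scale (absolute for magnitudes <= 1)
expect_engine_matches_oracle <- function(params) {
  for (s in c("non_operative", "operative")) {
    out <- run_cohort(params, s, keep_trace = FALSE)
    orc <- oracle_totals(params, s)
    expect_lt(abs(out$total_cost - orc[["cost"]]),
              1e-9 * max(1, abs(orc[["cost"]])))
    expect_lt(abs(out$total_qalys - orc[["qalys"]]),
              1e-9 * max(1, abs(orc[["qalys"]])))
  }
}
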