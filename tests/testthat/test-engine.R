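base_cal <- base_case_parameters(calibrated = TRUE)

test_that("episode resolution is a proper distribution", {
  d <- resolve_episode(event_rates(0.038, 0.055, 0.154))
  expect_equal(sum(d), 1)
  expect_equal(d[["full_benefit"]], 1 - 0.038 - 0.055 - 0.154)
  expect_equal(resolve_episode(event_rates(0, 0, 0))[["full_benefit"]], 1)
  d2 <- resolve_episode(event_rates(0.096, 0.031, 0.043))
  expect_equal(d2[["full_benefit"]], 0.83)
})

test_that("zero-event cohorts reduce to the closed-form utility schedule", {
  z <- degenerate_scenarios()$zero_events
  for (s in c("operative", "non_operative")) {
    out <- run_cohort(z$params, s)
    expect_equal(out$total_qalys, 0.25 * (0.7 + 0.8 + 6 * 0.9))
    expect_equal(out$total_qalys, z$expected$qalys[[s]])
    expect_equal(out$total_cost, z$expected$cost[[s]])
  }
})

test_that("base-case QALY totals land on the published values", {
  out <- run_strategies(base_cal)
  expect_lt(abs(out$non_operative$total_qalys - 1.69), 0.02)
  expect_lt(abs(out$operative$total_qalys - 1.67), 0.02)
  inc <- out$operative$total_qalys - out$non_operative$total_qalys
  expect_lt(inc, 0)
  expect_lt(abs(inc - (-0.02)), 0.01)
})

test_that("cohort trace conserves occupancy and accrues per cycle", {
  out <- run_cohort(base_cal, "non_operative")
  tr <- tidy(out)
  sums <- tapply(tr$occupancy, tr$cycle, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  expect_true(all(tr$occupancy >= 0 & tr$occupancy <= 1))
  expect_equal(sort(unique(tr$cycle)), 0:8)
  # accruals are non-negative and total to the outcome
  percyc <- unique(tr[, c("cycle", "cycle_cost", "cycle_qalys")])
  expect_true(all(percyc$cycle_cost >= 0 & percyc$cycle_qalys >= 0))
  expect_equal(sum(percyc$cycle_cost), out$total_cost)
  expect_equal(sum(percyc$cycle_qalys), out$total_qalys)
  # structural upper bound: full-benefit utility over the whole horizon
  expect_lte(out$total_qalys, 0.9 * 2)
  expect_gte(out$total_cost, episode_cost_total(base_cal, "non_operative"))
})

test_that("engine agrees with exhaustive branch enumeration", {
  expect_engine_matches_oracle(base_cal)
  expect_engine_matches_oracle(base_case_parameters(calibrated = FALSE))
  # single-cycle complication persistence variant
  p1 <- base_cal
  p1$utilities$complication_persistence <- "single_cycle"
  expect_engine_matches_oracle(p1)
  # non-operative utility decrement in force
  p2 <- param_set(base_cal, "utilities.nonoperative_ratio", 0.97)
  expect_engine_matches_oracle(p2)
  for (seed in 1:30) {
    expect_engine_matches_oracle(random_scenario(seed))
  }
})

test_that("re-rupture mass follows the truncated geometric series", {
  q_op <- 0.038
  expect_equal(expected_rerupture_mass(base_cal, "operative"),
               q_op * sum(q_op^(0:6)))
  expect_equal(expected_rerupture_mass(base_cal, "non_operative"),
               0.096 * sum(q_op^(0:6)))
  z <- degenerate_scenarios()$zero_events
  expect_equal(expected_rerupture_mass(z$params, "operative"), 0)
  # printed-value sanity: about 4.0% and 10.0% of the cohorts
  expect_lt(abs(expected_rerupture_mass(base_cal, "operative") - 0.0395), 1e-3)
  expect_lt(abs(expected_rerupture_mass(base_cal, "non_operative") - 0.0998), 1e-3)
})

test_that("outcomes respond monotonically to rates and costs", {
  ref <- run_cohort(base_cal, "non_operative", keep_trace = FALSE)
  for (path in c("rates_nonoperative.rerupture", "rates_nonoperative.major",
                 "rates_nonoperative.minor")) {
    up <- run_cohort(param_set(base_cal, path, param_get(base_cal, path) + 0.05),
                     "non_operative", keep_trace = FALSE)
    expect_lte(up$total_qalys, ref$total_qalys)
  }
  for (path in c("episode_costs.non_operative.surgeon",
                 "episode_costs.rerupture_surgery.hospitalization",
                 "wage.hourly_wage")) {
    up <- run_cohort(param_set(base_cal, path, param_get(base_cal, path) + 100),
                     "non_operative", keep_trace = FALSE)
    expect_gte(up$total_cost, ref$total_cost)
  }
})

test_that("total cost is affine in each cost component", {
  paths <- c("episode_costs.operative.hospitalization",
             "complication_costs.major", "complication_costs.minor",
             "episode_costs.rerupture_surgery.surgeon")
  for (path in paths) {
    v0 <- param_get(base_cal, path)
    cost_at <- function(v) run_cohort(param_set(base_cal, path, v),
                                      "operative", keep_trace = FALSE)$total_cost
    c0 <- cost_at(abs(v0)); c1 <- cost_at(abs(v0) + 100); c2 <- cost_at(abs(v0) + 200)
    slope <- (c1 - c0) / 100
    expect_gte(slope, 0)
    expect_lt(abs((c2 - c1) / 100 - slope), 1e-9)
  }
})

test_that("outcomes converge to the closed form as event rates vanish", {
  p <- base_case_parameters(calibrated = FALSE)
  for (eps in c(1e-3, 1e-6, 1e-9)) {
    p$rates_nonoperative[] <- eps
    p$rates_operative[] <- eps
    out <- run_cohort(validate_parameters(p), "non_operative", keep_trace = FALSE)
    expect_lt(abs(out$total_qalys - 1.725), 10 * eps)
    expect_lt(abs(out$total_cost - episode_cost_total(p, "non_operative")),
              1e6 * eps)
  }
})
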