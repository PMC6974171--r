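base_uncal <- base_case_parameters(calibrated = FALSE)

test_that("operative rates derive from risk ratio times non-operative rate", {
  rr <- base_uncal$relative_risks
  nonop <- base_uncal$rates_nonoperative
  derived <- derive_operative_rates(rr, nonop)
  expect_equal(unname(derived[["rerupture"]]), 0.40 * 0.096)
  expect_equal(round(100 * derived[["rerupture"]], 1), 3.8)
  expect_equal(unname(derived[["major"]]), 1.79 * 0.031)
  expect_equal(round(100 * derived[["major"]], 1), 5.5)

  # identity risk ratios reproduce the input rates
  ident <- setNames(rep(1, 3), c("rerupture", "major", "minor"))
  expect_equal(derive_operative_rates(ident, nonop), nonop)

  # homogeneity: scaling a non-operative rate scales the derived rate
  for (k in c(0.5, 2)) {
    scaled <- nonop
    scaled[["rerupture"]] <- k * nonop[["rerupture"]]
    expect_equal(derive_operative_rates(rr, scaled)[["rerupture"]],
                 k * derived[["rerupture"]])
  }

  big <- setNames(c(8, 8, 8), c("rerupture", "major", "minor"))
  expect_error(derive_operative_rates(big, nonop), "sum")
})

test_that("episode cost totals reproduce the printed cost table", {
  # printed component costs are exact; printed totals are rounded (+/- $2)
  expect_lt(abs(episode_cost_total(base_uncal, "operative") - 12609), 2)
  expect_lt(abs(episode_cost_total(base_uncal, "non_operative") - 11386), 2)
  expect_lt(abs(episode_cost_total(base_uncal, "rerupture_surgery") - 13408), 2)
  expect_equal(episode_cost_total(base_uncal, "operative"),
               3145 + 810 + 821 + 7834)
  # additivity: total is the sum of direct components plus missed work
  expect_equal(episode_cost_total(base_uncal, "operative", include_missed_work = FALSE),
               3145 + 810 + 821)
  zero <- base_uncal
  zero$episode_costs[zero$episode_costs$episode == "non_operative",
                     c("hospitalization", "surgeon", "physical_therapy", "weeks_missed")] <-
    list(0, 0, 0, 0)
  expect_equal(episode_cost_total(zero, "non_operative"), 0)
})

test_that("wage arithmetic is self-consistent across the cost table", {
  w <- implied_hourly_wage(7834, 8, 40)
  expect_equal(w, 24.48125)
  # the two arms imply the same hourly wage
  expect_lt(abs(implied_hourly_wage(10282, 10.5, 40) - w), 0.01)
  expect_lt(abs(missed_work_cost(10.5, wage_model(w)) - 10282), 1)
  expect_lt(abs(missed_work_cost(8, wage_model(w)) - 7834), 1)
  expect_equal(missed_work_cost(0, wage_model(w)), 0)
  expect_equal(implied_hourly_wage(0, 8, 40), 0)
  expect_error(implied_hourly_wage(100, 0, 40), "> 0")

  # round trip: implied_hourly_wage o missed_work_cost is the identity
  for (seed in 1:20) {
    set.seed(seed)
    wage <- runif(1, 1, 100)
    weeks <- runif(1, 0.1, 30)
    hrs <- runif(1, 10, 60)
    wm <- wage_model(wage, hrs)
    expect_equal(implied_hourly_wage(missed_work_cost(weeks, wm), weeks, hrs),
                 wage)
  }
})

test_that("parameter invariants are enforced with named errors", {
  expect_error(event_rates(0.5, 0.4, 0.2), "sum")
  expect_error(event_rates(-0.1, 0, 0), "\\[0, 1\\]")
  expect_error(relative_risks("rerupture", 0.4, 0.5, 1.3), "ci_low")
  expect_error(episode_costs("non_operative", 100, 283, 821, 10.5),
               "hospitalization")
  expect_error(utility_schedule(c(0.9, 0.7, 0.8)), "non-decreasing")
  expect_error(utility_schedule(minor_multiplier = 1.2), "multipliers")
  expect_error(run_settings(n_cycles = 0), "n_cycles")

  bad <- base_uncal
  bad$rates_operative[["minor"]] <- 0.99
  expect_error(validate_parameters(bad), "rates_operative")
})

test_that("parameter paths read and write every model quantity", {
  p <- base_uncal
  expect_equal(param_get(p, "episode_costs.operative.hospitalization"), 3145)
  expect_equal(param_get(p, "rates_nonoperative.rerupture"), 0.096)
  expect_equal(param_get(p, "relative_risks.minor.ci_high"), 31.61)
  expect_equal(param_get(p, "utilities.recovery.2"), 0.8)
  expect_equal(param_get(p, "wage.hourly_wage"), 24.48125)

  p2 <- param_set(p, "episode_costs.operative.hospitalization", 2000)
  expect_equal(param_get(p2, "episode_costs.operative.hospitalization"), 2000)
  expect_equal(param_get(p, "episode_costs.operative.hospitalization"), 3145)
  expect_error(param_set(p, "no.such.path", 1), "unknown")
  expect_error(param_set(p, "rates_nonoperative.rerupture", 1.5), "\\[0, 1\\]")

  # setting inputs of derived operative rates re-derives them
  pd <- base_case_parameters(calibrated = FALSE, derive_rates = TRUE)
  pd2 <- param_set(pd, "rates_nonoperative.rerupture", 0.2)
  expect_equal(param_get(pd2, "rates_operative.rerupture"), 0.4 * 0.2)
})

test_that("parameter files round-trip through the YAML dialect", {
  path <- withr::local_tempfile(fileext = ".yaml")
  write_parameters(base_uncal, path)
  back <- read_parameters(path)
  expect_equal(back$rates_operative, base_uncal$rates_operative)
  expect_equal(back$episode_costs, base_uncal$episode_costs)
  expect_equal(back$utilities, base_uncal$utilities)
  out1 <- run_cohort(base_uncal, "operative", keep_trace = FALSE)
  out2 <- run_cohort(back, "operative", keep_trace = FALSE)
  expect_identical(out1$total_cost, out2$total_cost)
  expect_identical(out1$total_qalys, out2$total_qalys)

  broken <- yaml::read_yaml(path)
  broken$rates_nonoperative <- NULL
  path2 <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(broken, path2)
  expect_error(read_parameters(path2), "missing required fields")
})
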