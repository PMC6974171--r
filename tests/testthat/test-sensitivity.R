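base_cal <- base_case_parameters(calibrated = TRUE)

test_that("hospitalization sweep flips the preferred strategy exactly once", {
  sw <- one_way_sweep(base_cal, "episode_costs.operative.hospitalization",
                      0, 6000, n_points = 61, wtp = 50000)
  expect_equal(nrow(sw), 61)
  flips <- sum(head(sw$preferred, -1) != sw$preferred[-1])
  expect_equal(flips, 1)
  # operative preferred at low hospitalization cost (cheaper surgery)
  expect_identical(sw$preferred[1], "operative")
  expect_identical(sw$preferred[61], "non_operative")
  # cost difference is affine in the swept component
  d2 <- diff(diff(sw$delta_cost))
  expect_lt(max(abs(d2)), 1e-8)
})

test_that("utility-decrement sweep moves incremental QALYs monotonically", {
  sw <- one_way_sweep(base_cal, "utilities.nonoperative_ratio",
                      0.95, 1, n_points = 11, wtp = 50000)
  # larger decrement (smaller ratio) favours operative: delta_qalys
  # (operative - non-operative) strictly decreasing in the ratio
  expect_true(all(diff(sw$delta_qalys) < 0))
  expect_identical(sw$preferred[1], "operative")
  expect_identical(sw$preferred[11], "non_operative")
})

test_that("degenerate sweep ranges yield repeated rows and invalid ranges fail fast", {
  sw <- one_way_sweep(base_cal, "wage.hourly_wage", 24.48125, 24.48125,
                      n_points = 3)
  expect_equal(nrow(sw), 3)
  expect_equal(length(unique(sw$delta_cost)), 1)
  expect_error(one_way_sweep(base_cal, "rates_nonoperative.rerupture", 0.5, 1.2),
               "sum|\\[0, 1\\]")
})

test_that("published deterministic thresholds are recovered", {
  th_hosp <- find_threshold(base_cal, "episode_costs.operative.hospitalization",
                            bounds = c(0, 3145), criterion = "cost_parity")
  expect_lt(abs(th_hosp$threshold - (3145 - 523.34)), 0.05)
  expect_lt(abs(th_hosp$threshold - 2621), 5)
  expect_identical(th_hosp$operative_preferred_when, "below")

  th_wage <- find_threshold(base_cal, "wage.hourly_wage",
                            bounds = c(24.48125, 100), criterion = "cost_parity")
  expect_equal(round(th_wage$threshold), 29)
  expect_identical(th_wage$operative_preferred_when, "above")

  th_u <- find_threshold(base_cal, "utilities.nonoperative_ratio",
                         bounds = c(0.9, 1), wtp = 50000, criterion = "nmb_flip")
  decrement_pct <- 100 * (1 - th_u$threshold)
  expect_equal(round(decrement_pct), 2)
  expect_identical(th_u$operative_preferred_when, "below")
})

test_that("thresholds verify by direct evaluation on either side", {
  cases <- list(
    list(path = "episode_costs.operative.hospitalization", bounds = c(0, 3145),
         criterion = "cost_parity"),
    list(path = "wage.hourly_wage", bounds = c(24.48125, 100),
         criterion = "cost_parity"),
    list(path = "utilities.nonoperative_ratio", bounds = c(0.9, 1),
         criterion = "nmb_flip")
  )
  margin <- function(params, path, v, criterion) {
    p <- param_set(params, path, v)
    out <- run_strategies(p, keep_trace = FALSE)
    dc <- out$operative$total_cost - out$non_operative$total_cost
    dq <- out$operative$total_qalys - out$non_operative$total_qalys
    if (criterion == "cost_parity") -dc else 50000 * dq - dc
  }
  for (cs in cases) {
    th <- find_threshold(base_cal, cs$path, cs$bounds, wtp = 50000,
                         criterion = cs$criterion)
    tol <- if (cs$criterion == "cost_parity") 0.01 else 1e-4
    m_lo <- margin(base_cal, cs$path, th$threshold - 2 * tol, cs$criterion)
    m_hi <- margin(base_cal, cs$path, th$threshold + 2 * tol, cs$criterion)
    expect_true(sign(m_lo) != sign(m_hi))
  }
  expect_error(find_threshold(base_cal, "episode_costs.operative.hospitalization",
                              bounds = c(3000, 3145)), "no threshold")
})

test_that("tornado ranks the published drivers and leaves the decision rate-robust", {
  torn <- report_dsa(base_cal)$tornado
  # relative utilities are the single most influential parameter
  expect_identical(torn$parameter[1], "utilities.nonoperative_ratio")
  # hospitalization cost and the wage outrank the re-rupture and minor rates
  rank_of <- function(p) which(torn$parameter == p)
  expect_lt(rank_of("episode_costs.operative.hospitalization"),
            rank_of("rates_operative.rerupture"))
  expect_lt(rank_of("episode_costs.operative.hospitalization"),
            rank_of("rates_operative.minor"))
  expect_lt(rank_of("wage.hourly_wage"), rank_of("rates_operative.rerupture"))
  expect_lt(rank_of("wage.hourly_wage"), rank_of("rates_operative.minor"))
  # varying event rates across their CI-implied ranges never changes the
  # decision
  rate_rows <- torn[grepl("^rates_operative", torn$parameter), ]
  expect_equal(nrow(rate_rows), 3)
  expect_true(all(rate_rows$preferred_at_low == "non_operative"))
  expect_true(all(rate_rows$preferred_at_high == "non_operative"))
  # single-spec tornado is a single-row table
  single <- tornado(base_cal, tibble::tibble(
    parameter = "wage.hourly_wage", low = 20, high = 30))
  expect_equal(nrow(single), 1)
})
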