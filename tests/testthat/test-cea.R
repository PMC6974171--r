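base_cal <- base_case_parameters(calibrated = TRUE)
base_out <- run_strategies(base_cal)

test_that("the base case classifies operative repair as dominated", {
  cmp <- compare_strategies(base_out$non_operative, base_out$operative)
  expect_equal(cmp$delta_cost, 523.34, tolerance = 1e-6)
  expect_lt(cmp$delta_qalys, 0)
  expect_lt(abs(cmp$delta_qalys - (-0.02)), 0.01)
  expect_identical(cmp$classification, "reference_dominates")
  expect_true(is.na(cmp$icer))
  expect_true(all(cmp$nmb$preferred == "non_operative"))
  # NMB difference at lambda = 50,000 from the published increments
  expect_lt(abs(-cmp$nmb$nmb_difference[cmp$nmb$wtp == 50000] -
                  (50000 * (-cmp$delta_qalys) + 523.34)), 1e-6)
})

test_that("net monetary benefit is linear in the threshold", {
  o <- base_out$non_operative
  expect_equal(nmb(o, 0), -o$total_cost)
  expect_equal(nmb(o, 100000) - nmb(o, 50000), 50000 * o$total_qalys)
  expect_error(nmb(o, -1), ">= 0")
})

test_that("identical outcomes are classified equivalent with reference preferred", {
  eq <- degenerate_scenarios()$equal_arms
  out <- run_strategies(eq$params)
  cmp <- compare_strategies(out$non_operative, out$operative)
  expect_identical(cmp$classification, "equivalent")
  expect_equal(cmp$delta_cost, 0)
  expect_equal(cmp$delta_qalys, 0)
  expect_true(all(cmp$nmb$preferred == "non_operative"))
})

test_that("comparison is antisymmetric under swapping the strategies", {
  for (seed in c(2, 5, 8, 13)) {
    p <- random_scenario(seed)
    out <- run_strategies(p, keep_trace = FALSE)
    ab <- compare_strategies(out$non_operative, out$operative, c(0, 5e4, 1e5))
    ba <- compare_strategies(out$operative, out$non_operative, c(0, 5e4, 1e5))
    expect_equal(ab$delta_cost, -ba$delta_cost)
    expect_equal(ab$delta_qalys, -ba$delta_qalys)
    expect_equal(ab$nmb$nmb_difference, -ba$nmb$nmb_difference)
    mirror <- c(reference_dominates = "comparator_dominates",
                comparator_dominates = "reference_dominates",
                trade_off = "trade_off", equivalent = "equivalent")
    expect_identical(ba$classification, unname(mirror[ab$classification]))
    if (ab$classification == "trade_off") expect_equal(ab$icer, ba$icer)
  }
})

test_that("for trade-offs the NMB decision matches the ICER rule", {
  # construct a genuine trade-off: cheaper operative care, fewer QALYs not
  # applicable -> instead raise non-operative costs so operative costs more
  # but also add a utility advantage to the operative arm
  p <- param_set(base_cal, "utilities.nonoperative_ratio", 0.95)
  out <- run_strategies(p, keep_trace = FALSE)
  grid <- seq(0, 2e5, by = 1e4)
  cmp <- compare_strategies(out$non_operative, out$operative, grid)
  expect_identical(cmp$classification, "trade_off")
  expect_gt(cmp$delta_qalys, 0)
  expect_equal(cmp$icer, cmp$delta_cost / cmp$delta_qalys)
  by_icer <- ifelse(grid > cmp$icer, "operative", "non_operative")
  expect_identical(cmp$nmb$preferred, by_icer)

  # the textbook arithmetic case: $1000 for 0.02 QALYs is $50,000/QALY
  a <- base_out$non_operative
  b <- a
  b$strategy <- "operative"
  b$total_cost <- a$total_cost + 1000
  b$total_qalys <- a$total_qalys + 0.02
  cmp2 <- compare_strategies(a, b, c(49000, 50000, 51000))
  expect_equal(cmp2$icer, 50000)
  expect_identical(cmp2$nmb$preferred, c("non_operative", "non_operative", "operative"))
})

test_that("scaling all costs rescales the comparison coherently", {
  k <- 3
  p <- base_cal
  cols <- c("hospitalization", "surgeon", "physical_therapy")
  p$episode_costs[cols] <- lapply(p$episode_costs[cols], function(x) k * x)
  p$wage$hourly_wage <- k * p$wage$hourly_wage
  p$complication_costs$major <- k * p$complication_costs$major
  p$complication_costs$minor <- k * p$complication_costs$minor
  out <- run_strategies(p, keep_trace = FALSE)
  cmp0 <- compare_strategies(base_out$non_operative, base_out$operative, 5e4)
  cmpk <- compare_strategies(out$non_operative, out$operative, k * 5e4)
  expect_equal(cmpk$delta_cost, k * cmp0$delta_cost)
  expect_equal(cmpk$delta_qalys, cmp0$delta_qalys)
  expect_equal(cmpk$nmb$nmb_difference, k * cmp0$nmb$nmb_difference)
})

test_that("tidy and glance surface the comparison as tibbles", {
  cmp <- compare_strategies(base_out$non_operative, base_out$operative)
  td <- tidy(cmp)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 2)
  expect_equal(td$total_cost, c(13413.04, 13936.38), tolerance = 1e-6)
  gl <- glance(cmp)
  expect_identical(gl$classification, "reference_dominates")
  gout <- glance(base_out$operative)
  expect_equal(gout$total_cost, 13936.38, tolerance = 1e-6)
})
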