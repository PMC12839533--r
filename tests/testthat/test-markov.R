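test_that("annual-to-monthly conversion preserves the annual probability", {
  expect_equal(annual_to_monthly_prob(0), 0)
  expect_equal(annual_to_monthly_prob(1), 1)
  expect_equal(annual_to_monthly_prob(0.12), 0.010596241035319,
               tolerance = 1e-12)
  # twelve consecutive monthly applications reproduce the annual q
  for (q in c(1e-5, 0.01, 0.12, 0.5, 0.97)) {
    pm <- annual_to_monthly_prob(q)
    expect_equal(1 - (1 - pm)^12, q, tolerance = 1e-9)
  }
  expect_error(annual_to_monthly_prob(1.1), "\\[0,1\\]")
})

test_that("post-discharge utility applies age bands and 4-year decrements", {
  u <- base_params()$utilities
  expect_equal(postdischarge_utility(59.0, 0.5, u), 0.84 - 0.130)
  expect_equal(postdischarge_utility(62.0, 3.5, u), 0.82 - 0.026)
  expect_equal(postdischarge_utility(63.0, 4.5, u), 0.820)
  # band boundaries are closed-open: age 60 belongs to the 60-69 band
  expect_equal(postdischarge_utility(60.0, 10, u), 0.82)
  expect_equal(postdischarge_utility(80.0, 10, u), 0.74)
  expect_equal(postdischarge_utility(22.0, 10, u), 0.87)
  # floor at zero
  u2 <- u
  u2$postdischarge_disutility_by_year <- c(0.95, 0, 0, 0)
  expect_equal(postdischarge_utility(59, 0.2, u2), 0)
  expect_error(postdischarge_utility(59, -1, u), ">= 0")
})

test_that("cohort life years match the constant-hazard closed form", {
  u <- neutral_utilities()
  st <- neutral_settings(start_age = 50, horizon_age = 1e4)
  n_cycles <- (1e4 - 50) * 12  # cycles until the horizon
  for (pm in c(1e-4, 1e-3, 0.01, 0.05, 0.2)) {
    lt <- make_constant_hazard_table(annual_q_for_monthly(pm), 0, 1e4)
    tr <- run_cohort(50, lt, u, st)
    tot <- discounted_survivor_totals(tr)
    expect_equal(tot$ly, constant_hazard_expected_ly(pm, n_cycles),
                 tolerance = 1e-9)
    expect_equal(tot$qaly_discounted, tot$ly, tolerance = 1e-12)
  }
})

test_that("immediate death yields half a cycle of life", {
  lt <- life_table(50:60, rep(1, 11))
  st <- neutral_settings(start_age = 50, horizon_age = 60)
  tr <- run_cohort(50, lt, neutral_utilities(), st)
  tot <- discounted_survivor_totals(tr)
  expect_equal(tot$ly, 0.5 / 12, tolerance = 1e-12)
})

test_that("twelve monthly cycles reproduce the annual death probability", {
  q <- 0.137
  lt <- make_constant_hazard_table(q, 40, 400)
  st <- neutral_settings(start_age = 40, horizon_age = 400)
  tr <- run_cohort(40, lt, neutral_utilities(), st)
  dead_12 <- 1 - tr$alive[13]  # alive at the start of cycle 12
  expect_equal(dead_12, q, tolerance = 1e-12)
})

test_that("the trace satisfies the cohort invariants", {
  lt <- bundled_lt()
  p <- base_params()
  tr <- run_cohort(58.6 + 2 / 12, lt, p$utilities, p$settings)
  expect_equal(tr$alive[1], 1)
  expect_true(all(diff(tr$alive) <= 0))
  expect_true(all(diff(tr$discount) <= 0))
  expect_true(all(tr$ly_inc >= 0 & tr$qaly_inc >= 0))
  expect_true(all(tr$alive >= 0 & tr$alive <= 1))
  expect_true(max(tr$age) < p$settings$horizon_age + 1 / 12)
  # discounted never exceeds undiscounted
  tot <- discounted_survivor_totals(tr)
  expect_lt(tot$ly_discounted, tot$ly)
  expect_lte(tot$qaly_discounted, tot$ly_discounted)
})

test_that("discounted life years match an independent geometric series", {
  # constant monthly hazard p, discount r: closed-form geometric sum of the
  # half-cycle-corrected, discounted increments
  p <- 0.005
  r <- 0.03
  u <- neutral_utilities()
  st <- neutral_settings(start_age = 30, horizon_age = 1e4, discount = r)
  lt <- make_constant_hazard_table(annual_q_for_monthly(p), 0, 1e4)
  tot <- discounted_survivor_totals(run_cohort(30, lt, u, st))

  g <- (1 + r)^(-1 / 12)
  x <- (1 - p) * g
  n <- (1e4 - 30) * 12
  t0 <- st$acute_phase_cycles
  oracle <- (1 + r)^(-t0 / 12) * (1 + (1 - p)) / 24 * (1 - x^n) / (1 - x)
  expect_equal(tot$ly_discounted, oracle, tolerance = 1e-9)

  # zero discount: discounted and undiscounted life years coincide
  st0 <- neutral_settings(start_age = 30, horizon_age = 1e4)
  tot0 <- discounted_survivor_totals(run_cohort(30, lt, u, st0))
  expect_equal(tot0$ly_discounted, tot0$ly, tolerance = 1e-12)
})

test_that("QALYs respond monotonically to discounting and utilities", {
  lt <- bundled_lt()
  p <- base_params()
  qaly_at_rate <- function(r) {
    st <- p$settings
    st$annual_discount_rate <- r
    discounted_survivor_totals(
      run_cohort(58.77, lt, p$utilities, st))$qaly_discounted
  }
  rates <- c(0, 0.015, 0.03, 0.05, 0.08)
  expect_true(all(diff(vapply(rates, qaly_at_rate, numeric(1))) < 0))

  bump_band <- function(delta) {
    u <- p$utilities
    for (i in seq_along(u$age_band_utilities)) {
      u$age_band_utilities[[i]]$utility <-
        min(u$age_band_utilities[[i]]$utility + delta, 1)
    }
    discounted_survivor_totals(
      run_cohort(58.77, lt, u, p$settings))$qaly_discounted
  }
  expect_lt(bump_band(-0.1), bump_band(0))
  expect_lt(bump_band(0), bump_band(0.1))

  bump_dis <- function(delta) {
    u <- p$utilities
    u$postdischarge_disutility_by_year <-
      u$postdischarge_disutility_by_year + delta
    discounted_survivor_totals(
      run_cohort(58.77, lt, u, p$settings))$qaly_discounted
  }
  expect_lt(bump_dis(0.05), bump_dis(0))
})

test_that("cohort runs reject incoherent ages", {
  lt <- bundled_lt()
  p <- base_params()
  expect_error(run_cohort(101, lt, p$utilities, p$settings), "horizon")
  lt50 <- make_constant_hazard_table(0.1, 50, 100)
  expect_error(run_cohort(40, lt50, p$utilities, p$settings), "first age")
})
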