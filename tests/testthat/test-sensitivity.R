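test_that("one-way DSA moves the ICER in the expected directions", {
  p <- base_params()
  lt <- bundled_lt()
  res <- one_way_dsa(p, lt)
  row <- function(path) res[res$parameter == path, ]

  vilo <- row("arms.vilobelimab.survival_60d")
  expect_equal(vilo$direction, "decrease")  # better survival, lower ICER
  expect_gt(vilo$icer_at_low, vilo$icer_at_high)

  soc <- row("arms.soc.survival_60d")
  expect_equal(soc$direction, "increase")
  age <- row("settings.start_age")
  expect_equal(age$direction, "increase")

  # base ICER lies between the extremes for these monotone parameters
  base_icer <- run_cea(p, lt)$incremental$icer
  for (pp in c("arms.vilobelimab.survival_60d", "arms.soc.survival_60d",
               "settings.start_age")) {
    r <- row(pp)
    expect_gte(base_icer, min(r$icer_at_low, r$icer_at_high))
    expect_lte(base_icer, max(r$icer_at_low, r$icer_at_high))
  }

  # results arrive sorted by descending span
  expect_true(all(diff(res$span) <= 0))
  expect_true(all(res$span >= 0))

  # the ICU cost is common to both arms: varying it cannot move the ICER
  expect_lt(row("costs.icu_cost")$span, 1e-6)
})

test_that("degenerate ranges and missing ranges are handled", {
  p <- base_params()
  lt <- bundled_lt()
  i <- which(vapply(p$uncertainty, `[[`, character(1), "path") ==
               "arms.soc.rrt_days")
  p$uncertainty[[i]]$low <- 9.4
  p$uncertainty[[i]]$high <- 9.4
  res <- one_way_dsa(p, lt, "arms.soc.rrt_days")
  expect_equal(res$span, 0)
  expect_equal(res$icer_at_low, run_cea(p, lt)$incremental$icer)

  expect_error(one_way_dsa(p, lt, "utilities.mv_disutility"), "no low/high")
})

test_that("tornado_table keeps the widest parameters with stable ties", {
  res <- data.frame(
    parameter = c("b", "a", "c"), low_value = 0, base_value = 1,
    high_value = 2, icer_at_low = c(5, 5, 1), icer_at_high = c(9, 9, 2),
    direction = "increase", span = c(4, 4, 1), stringsAsFactors = FALSE)
  res <- res[order(-res$span, res$parameter), ]
  expect_equal(tornado_table(res, 2)$parameter, c("a", "b"))  # tie: by path
  expect_equal(nrow(tornado_table(res, 0)), 0)
  expect_message(all_rows <- tornado_table(res, 10), "only 3")
  expect_equal(nrow(all_rows), 3)
})

test_that("PSA draws are reproducible and respect fixed parameters", {
  p <- base_params()
  lt <- bundled_lt()
  a <- sample_psa(p, lt, n = 50, seed = 7)
  b <- sample_psa(p, lt, n = 50, seed = 7)
  expect_identical(a, b)
  c2 <- sample_psa(p, lt, n = 50, seed = 8)
  expect_false(identical(a$draws, c2$draws))

  # cost parameters never appear among the sampled columns
  expect_false(any(grepl("^costs\\.", a$sampled_paths)))
  # age draws honour the truncation bounds
  age <- a$draws[["settings.start_age"]]
  expect_true(all(age >= 22 & age <= 79))
})

test_that("a point-mass PSA reproduces the base case on every draw", {
  p <- point_mass_params()
  lt <- bundled_lt()
  base <- run_cea(p, lt)$incremental
  psa <- sample_psa(p, lt, n = 10, seed = 1)
  expect_equal(psa$draws$delta_cost, rep(base$delta_cost, 10))
  expect_equal(psa$draws$delta_qaly, rep(base$delta_qaly, 10))
})

test_that("the CEAC is a fraction of accepted draws, monotone for positive gains", {
  p <- base_params()
  lt <- bundled_lt()
  psa <- sample_psa(p, lt, n = 200, seed = 11)
  grid <- seq(0, 150000, by = 5000)
  cc <- ceac(psa, grid)
  expect_true(all(cc$fraction_accepted >= 0 & cc$fraction_accepted <= 1))
  # at WTP 0 the NMB reduces to -delta_cost: acceptance = cost-saving draws
  expect_equal(cc$fraction_accepted[1], mean(psa$draws$delta_cost < 0))
  # restricted to draws with positive QALY gains the curve is nondecreasing
  pos <- psa
  pos$draws <- pos$draws[pos$draws$delta_qaly > 0, ]
  cc_pos <- ceac(pos, grid)
  expect_true(all(diff(cc_pos$fraction_accepted) >= 0))
  # at infinite WTP acceptance converges to the positive-gain fraction
  cc_inf <- ceac(psa, 1e12)
  expect_equal(cc_inf$fraction_accepted, mean(psa$draws$delta_qaly > 0))
})

test_that("an infeasible distribution fails before any draw", {
  p <- base_params()
  i <- which(vapply(p$uncertainty, `[[`, character(1), "path") ==
               "utilities.mv_disutility")
  p$uncertainty[[i]]$sd <- 0.9  # sd^2 > mean(1-mean): no beta exists
  expect_error(sample_psa(p, bundled_lt(), n = 5, seed = 1), "infeasible")
})
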