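test_that("the bundled configuration carries the published base-case values", {
  p <- load_parameters(default_config_path())
  expect_s3_class(p, "cea_parameters")
  expect_named(p$arms, c("soc", "vilobelimab"))
  expect_equal(p$arms$vilobelimab$survival_60d, 0.82)
  expect_equal(p$arms$soc$survival_60d, 0.51)
  expect_equal(p$arms$vilobelimab$p_rrt, 0.096)
  expect_equal(p$arms$soc$p_rrt, 0.157)
  expect_equal(p$costs$icu_cost, 100461)
  expect_equal(p$costs$drug_cost_per_admin, 6350)
  expect_equal(p$settings$start_age, 58.6)
  expect_equal(p$utilities$mv_disutility, 0.56)
  expect_length(p$utilities$postdischarge_disutility_by_year, 4)
  expect_equal(p, default_parameters(), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("validation rejects out-of-range and malformed inputs by name", {
  p <- unclass(default_parameters())
  p$arms$vilobelimab$survival_60d <- 1.2
  expect_error(validate_parameters(p, on_inverted_range = "keep"),
               "survival_60d")

  p <- unclass(default_parameters())
  p$costs$icu_cost <- -1
  p$arms$soc$p_rrt <- 7
  err <- tryCatch(validate_parameters(p, on_inverted_range = "keep"),
                  error = conditionMessage)
  expect_match(err, "costs.icu_cost", fixed = TRUE)
  expect_match(err, "arms.soc.p_rrt", fixed = TRUE)

  p <- unclass(default_parameters())
  p$costs$parking <- 5
  expect_error(validate_parameters(p), "unknown key 'parking'")

  p <- unclass(default_parameters())
  p$settings$start_age <- NULL
  expect_error(validate_parameters(p), "start_age")

  p <- unclass(default_parameters())
  p$utilities$postdischarge_disutility_by_year <- c(0.1, 0.1)
  expect_error(validate_parameters(p), "exactly 4")

  p <- unclass(default_parameters())
  p$uncertainty[[1]]$path <- "arms.vilobelimab.no_such"
  expect_error(validate_parameters(p), "does not resolve")
})

test_that("parameters round-trip through save and load", {
  p <- default_parameters()
  f <- withr::local_tempfile(fileext = ".yaml")
  save_parameters(p, f)
  q <- load_parameters(f)
  expect_equal(unclass(q), unclass(p), tolerance = 1e-12)
})

test_that("dotted paths address scalars, including indexed entries", {
  p <- default_parameters()
  expect_equal(get_param(p, "arms.vilobelimab.survival_60d"), 0.82)
  expect_equal(get_param(p, "utilities.age_band_utilities.2.utility"), 0.84)
  expect_equal(get_param(p, "utilities.postdischarge_disutility_by_year.3"),
               0.062)
  q <- set_param(p, "settings.start_age", 40)
  expect_equal(q$settings$start_age, 40)
  expect_equal(p$settings$start_age, 58.6)  # original untouched
  q <- set_param(p, "utilities.age_band_utilities.5.utility", 0.7)
  expect_equal(q$utilities$age_band_utilities[[5]]$utility, 0.7)
  expect_error(get_param(p, "arms.nope.survival_60d"), "not found")
  expect_error(set_param(p, "costs.imaginary", 1), "not found")
})

test_that("ranges that fail to bracket their base value are handled per policy", {
  # the published intervention RRT-duration range (7.8-8.8 around base 6.8)
  p <- unclass(default_parameters())
  i <- which(vapply(p$uncertainty, `[[`, character(1), "path") ==
               "arms.vilobelimab.rrt_days")
  p$uncertainty[[i]]$low <- 7.8
  p$uncertainty[[i]]$high <- 8.8

  expect_warning(fixed <- validate_parameters(p), "symmetric range")
  expect_equal(fixed$uncertainty[[i]]$low, 6.3)
  expect_equal(fixed$uncertainty[[i]]$high, 7.3)

  kept <- validate_parameters(p, on_inverted_range = "keep")
  expect_equal(kept$uncertainty[[i]]$low, 7.8)

  expect_error(validate_parameters(p, on_inverted_range = "error"),
               "outside range")
})
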