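# Shared fixtures, built in code. The bundled life table and config are read
# once per test run.

base_params <- function() default_parameters()

bundled_lt <- local({
  lt <- NULL
  function() {
    if (is.null(lt)) lt <<- read_life_table(default_life_table_path())
    lt
  }
})

# Settings/utilities that make QALYs collapse onto life years: utility 1
# everywhere, no disutility, no discounting.
neutral_utilities <- function() {
  list(
    age_band_utilities = list(list(min = 0, max = 10000, utility = 1)),
    mv_disutility = 0,
    postdischarge_disutility_by_year = c(0, 0, 0, 0)
  )
}

neutral_settings <- function(start_age = 50, horizon_age = 1e4,
                             discount = 0) {
  s <- default_parameters()$settings
  s$start_age <- start_age
  s$horizon_age <- horizon_age
  s$annual_discount_rate <- discount
  s
}

# annual q whose constant-hazard monthly equivalent is exactly p_monthly
annual_q_for_monthly <- function(p_monthly) 1 - (1 - p_monthly)^12

# Turn every sampled uncertainty spec into a point mass (degenerate PSA).
point_mass_params <- function(p = default_parameters()) {
  p$uncertainty <- lapply(p$uncertainty, function(sp) {
    sp$family <- "fixed"
    sp
  })
  p
}
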