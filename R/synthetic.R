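#' Synthetic constant-hazard life table
#'
#' Every age carries the same annual death probability (except the terminal
#' age, where `q = 1`). The Markov engine's life-year total from such a table
#' has the closed form given by [constant_hazard_expected_ly()], which makes
#' these tables exact oracles for the cohort engine.
#'
#' @param annual_q Annual death probability in (0, 1\].
#' @param start_age,terminal_age Integer age range, `start_age <
#'   terminal_age`.
#' @return A [life_table].
#' @export
make_constant_hazard_table <- function(annual_q, start_age = 0,
                                       terminal_age = 100) {
  if (!(annual_q > 0 && annual_q <= 1)) {
    stop("make_constant_hazard_table(): annual_q must be in (0,1]")
  }
  if (start_age >= terminal_age) {
    stop("make_constant_hazard_table(): start_age must be below terminal_age")
  }
  ages <- start_age:terminal_age
  q <- rep(annual_q, length(ages))
  q[length(q)] <- 1
  life_table(ages, q)
}

#' Closed-form life years for a constant monthly hazard
#'
#' Under a constant monthly death probability `p`, the half-cycle-corrected
#' life-year sum over `n_cycles` monthly cycles is
#' `(1 - (1-p)^n) * (1/p - 1/2) / 12` years; with `n_cycles = Inf` this is
#' `(1/p - 1/2) / 12`.
#'
#' @param p_monthly Monthly death probability in (0, 1\].
#' @param n_cycles Number of monthly cycles (may be `Inf`).
#' @return Expected life years.
#' @export
constant_hazard_expected_ly <- function(p_monthly, n_cycles = Inf) {
  stopifnot(p_monthly > 0, p_monthly <= 1, n_cycles >= 0)
  tail_mass <- if (is.finite(n_cycles)) (1 - p_monthly)^n_cycles else 0
  (1 - tail_mass) * (1 / p_monthly - 0.5) / 12
}

#' Synthetic Gompertz(-Makeham) life table
#'
#' Annual death probabilities from a hazard `h(x) = makeham + a * exp(b*x)`:
#' `q(x) = 1 - exp(-makeham - (a/b) * (exp(b*(x+1)) - exp(b*x)))` for
#' `b > 0`, collapsing to the constant-hazard `1 - exp(-makeham - a)` at
#' `b = 0`. The terminal age is forced to `q = 1`.
#'
#' @param a Baseline exponential hazard per year, positive.
#' @param b Log-hazard slope per year, nonnegative.
#' @param start_age,terminal_age Integer age range.
#' @param makeham Optional age-independent hazard component per year
#'   (default 0).
#' @return A [life_table].
#' @export
make_gompertz_table <- function(a, b, start_age = 0, terminal_age = 100,
                                makeham = 0) {
  if (a <= 0) stop("make_gompertz_table(): baseline hazard a must be positive")
  if (b < 0) stop("make_gompertz_table(): slope b must be nonnegative")
  if (makeham < 0) stop("make_gompertz_table(): makeham term must be nonnegative")
  if (start_age >= terminal_age) {
    stop("make_gompertz_table(): start_age must be below terminal_age")
  }
  ages <- start_age:terminal_age
  cum_h <- if (b > 0) {
    (a / b) * (exp(b * (ages + 1)) - exp(b * ages))
  } else {
    rep(a, length(ages))
  }
  q <- 1 - exp(-makeham - cum_h)
  q[length(q)] <- 1
  life_table(ages, q)
}

#' Random valid parameter fixture
#'
#' Draws a complete, internally consistent [cea_parameters] object within
#' physiologically and economically plausible bounds: 60-day survivals in
#' \[0.05, 0.95\] with the intervention at least as high as the reference,
#' costs in \[1e3, 2e5\], utilities in \[0.5, 1\]. Every fixture passes
#' [validate_parameters()] and yields a finite ICER or a dominance flag when
#' run against any life table covering its ages. Intended for property-style
#' testing; identical seeds give identical fixtures.
#'
#' @param seed Integer seed.
#' @return A validated `cea_parameters` object.
#' @export
make_parameter_fixture <- function(seed) {
  set.seed(seed)
  p <- default_parameters()
  s_ref <- stats::runif(1, 0.05, 0.90)
  s_int <- stats::runif(1, s_ref, 0.95)
  p$arms[[1]]$survival_60d <- s_ref
  p$arms[[2]]$survival_60d <- s_int
  p$arms[[1]]$p_rrt <- stats::runif(1, 0.02, 0.4)
  p$arms[[2]]$p_rrt <- stats::runif(1, 0.02, 0.4)
  p$arms[[1]]$rrt_days <- stats::runif(1, 1, 20)
  p$arms[[2]]$rrt_days <- stats::runif(1, 1, 20)
  p$arms[[2]]$n_drug_administrations <- stats::runif(1, 1, 8)
  p$costs$icu_cost <- stats::runif(1, 1e3, 2e5)
  p$costs$rrt_cost_per_day <- stats::runif(1, 1e3, 5e3)
  p$costs$drug_cost_per_admin <- stats::runif(1, 1e3, 1e4)
  for (i in seq_along(p$utilities$age_band_utilities)) {
    p$utilities$age_band_utilities[[i]]$utility <- stats::runif(1, 0.5, 1)
  }
  p$utilities$mv_disutility <- stats::runif(1, 0, 0.8)
  p$utilities$postdischarge_disutility_by_year <-
    sort(stats::runif(4, 0, 0.2), decreasing = TRUE)
  p$settings$start_age <- stats::runif(1, 30, 80)
  p$settings$annual_discount_rate <- stats::runif(1, 0, 0.05)
  # keep the bundled uncertainty ranges centred on the new base values
  for (i in seq_along(p$uncertainty)) {
    sp <- p$uncertainty[[i]]
    if (!is.null(sp$low)) {
      base <- get_param(p, sp$path)
      half <- max(0.1 * abs(base), 1e-3)
      if (sp$family %in% c("beta")) {
        half <- min(half, base / 2, (1 - base) / 2)
      }
      p$uncertainty[[i]]$low <- base - half
      p$uncertainty[[i]]$high <- base + half
    }
  }
  validate_parameters(unclass(p), on_inverted_range = "error")
}
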