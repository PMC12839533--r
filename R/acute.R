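#' Expected renal replacement therapy cost per patient
#'
#' @param p_rrt Probability of receiving renal replacement therapy.
#' @param rrt_days Mean duration of RRT in days among those treated.
#' @param cost_per_day Cost per day of RRT (USD).
#' @return Expected cost in USD: `p_rrt * rrt_days * cost_per_day`.
#' @export
expected_rrt_cost <- function(p_rrt, rrt_days, cost_per_day) {
  if (p_rrt < 0 || p_rrt > 1) stop("expected_rrt_cost(): p_rrt outside [0,1]")
  if (rrt_days < 0 || cost_per_day < 0) {
    stop("expected_rrt_cost(): negative input")
  }
  p_rrt * rrt_days * cost_per_day
}

#' Drug acquisition cost per patient
#'
#' @param n_administrations Mean number of administrations per treated
#'   patient (decimal allowed; 0 for the reference arm).
#' @param cost_per_admin Cost per administration (USD).
#' @return Total acquisition cost in USD.
#' @export
drug_acquisition_cost <- function(n_administrations, cost_per_admin) {
  if (n_administrations < 0 || cost_per_admin < 0) {
    stop("drug_acquisition_cost(): negative input")
  }
  n_administrations * cost_per_admin
}

#' Acute-phase (decision-tree) outcomes for one strategy
#'
#' Covers hospitalization through day 60 (`acute_phase_cycles` monthly
#' cycles). Expected cost is the full ICU hospitalization cost plus the
#' expected RRT cost plus drug acquisition, charged to every patient
#' regardless of survival. The in-hospital utility is the age-band utility at
#' entry minus the mechanical-ventilation disutility, floored at zero.
#' Survivors accrue the whole acute phase at that utility; decedents accrue
#' half of it (deaths assumed uniform over the phase). Discounting applies
#' per monthly cycle from model entry.
#'
#' @param arm One entry of `params$arms` (clinical parameters).
#' @param costs,utilities,settings Components of [cea_parameters].
#' @param strategy Strategy name carried through to the result.
#' @return An `acute_outcome` list: `strategy`, `expected_cost`,
#'   `survivor_fraction`, `acute_ly`, `acute_ly_discounted`, `acute_qaly`
#'   (discounted), `discharge_age`.
#' @export
acute_phase_outcomes <- function(arm, costs, utilities, settings,
                                 strategy = "strategy") {
  cost <- costs$icu_cost +
    expected_rrt_cost(arm$p_rrt, arm$rrt_days, costs$rrt_cost_per_day) +
    drug_acquisition_cost(arm$n_drug_administrations,
                          costs$drug_cost_per_admin)

  u_band <- .band_utility(settings$start_age, utilities$age_band_utilities)
  u_acute <- max(u_band - utilities$mv_disutility, 0)

  nc <- settings$acute_phase_cycles
  k <- seq_len(nc) - 1L
  df <- (1 + settings$annual_discount_rate)^(-k / 12)
  s <- arm$survival_60d
  occupancy <- s + (1 - s) / 2  # decedents accrue half the phase

  out <- list(
    strategy = strategy,
    expected_cost = cost,
    survivor_fraction = s,
    acute_ly = occupancy * nc / 12,
    acute_ly_discounted = occupancy * sum(df) / 12,
    acute_qaly = occupancy * u_acute * sum(df) / 12,
    discharge_age = settings$start_age + nc / 12
  )
  class(out) <- "acute_outcome"
  out
}

#' @export
print.acute_outcome <- function(x, ...) {
  cat(sprintf("<acute_outcome> %s: cost $%s, %.1f%% survive to discharge at age %.2f\n",
              x$strategy, format(round(x$expected_cost, 2), big.mark = ","),
              100 * x$survivor_fraction, x$discharge_age))
  cat(sprintf("  acute LY %.4f, QALY %.4f (discounted)\n",
              x$acute_ly, x$acute_qaly))
  invisible(x)
}
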