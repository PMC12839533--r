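#' Convert an annual death probability to a monthly one
#'
#' Uses the constant-hazard-within-year relation
#' `p_month = 1 - (1 - q_annual)^(1/12)`, so twelve consecutive monthly
#' applications reproduce the annual probability exactly.
#'
#' @param q_annual Annual probability (or vector of probabilities) in \[0,1\].
#' @return Monthly probability of the same event.
#' @export
annual_to_monthly_prob <- function(q_annual) {
  if (any(!is.finite(q_annual)) || any(q_annual < 0) || any(q_annual > 1)) {
    stop("annual_to_monthly_prob(): probabilities must lie in [0,1]")
  }
  1 - (1 - q_annual)^(1 / 12)
}

# Vectorised age-band utility lookup over the closed-open bands in the
# utility schedule. Ages past the last band take the last band's utility.
.band_utility <- function(age, bands) {
  mins <- vapply(bands, `[[`, numeric(1), "min")
  vals <- vapply(bands, `[[`, numeric(1), "utility")
  idx <- findInterval(age, mins)
  idx[idx < 1L] <- 1L
  vals[idx]
}

#' Health-state utility after hospital discharge
#'
#' The age-band utility at the current age, minus the post-discharge
#' mechanical-ventilation disutility for the first four years (the year-k
#' decrement applies on `[k-1, k)` years since discharge), floored at zero.
#'
#' @param age Current age in years (vectorised).
#' @param years_since_discharge Nonnegative years since discharge
#'   (vectorised).
#' @param utilities Utility schedule component of [cea_parameters].
#' @return Utility value(s) in \[0,1\].
#' @export
postdischarge_utility <- function(age, years_since_discharge, utilities) {
  if (any(years_since_discharge < 0)) {
    stop("postdischarge_utility(): years_since_discharge must be >= 0")
  }
  u <- .band_utility(age, utilities$age_band_utilities)
  yr <- floor(years_since_discharge) + 1
  dis <- ifelse(yr <= 4, utilities$postdischarge_disutility_by_year[pmin(yr, 4)], 0)
  pmax(u - dis, 0)
}

# Core cohort engine, fully vectorised. Returns per-cycle vectors; both
# run_cohort() (audit trace) and the PSA fast path build on it.
.cohort_core <- function(discharge_age, lt, utilities, settings) {
  horizon <- settings$horizon_age
  r <- settings$annual_discount_rate
  t0 <- settings$acute_phase_cycles
  if (discharge_age >= horizon) {
    stop("discharge age ", discharge_age, " is at or beyond the horizon age ",
         horizon)
  }
  term <- lt$age[nrow(lt)]
  if (floor(discharge_age) < lt$age[1]) {
    stop("discharge age ", discharge_age, " below the life table's first age ",
         lt$age[1])
  }
  n <- ceiling((min(horizon, term + 1) - discharge_age) * 12 - 1e-9)
  k <- seq_len(n) - 1L
  age <- discharge_age + k / 12
  look <- pmin(floor(age + 1e-9), term)
  q <- lt$q[look - lt$age[1] + 1L]
  pm <- 1 - (1 - q)^(1 / 12)
  alive_end <- cumprod(1 - pm)
  alive_start <- c(1, alive_end[-n])

  # truncate once the cohort is numerically extinct
  last <- which(alive_start < 1e-12)
  if (length(last) > 0L) {
    n <- last[1] - 1L
    if (n == 0L) n <- 1L
    k <- k[seq_len(n)]
    age <- age[seq_len(n)]
    alive_start <- alive_start[seq_len(n)]
    alive_end <- alive_end[seq_len(n)]
  }

  ly_inc <- (alive_start + alive_end) / 2 / 12  # half-cycle correction
  u <- postdischarge_utility(age, k / 12, utilities)
  df <- (1 + r)^(-(t0 + k) / 12)
  list(cycle = k, age = age, alive = alive_start, alive_end = alive_end,
       utility = u, discount = df, ly_inc = ly_inc)
}

#' Run the post-discharge Markov cohort model
#'
#' Two-state (alive/dead) cohort simulation in monthly cycles. The monthly
#' death probability comes from the life table row for the cohort's current
#' integer age via [annual_to_monthly_prob()]. Life-year increments use the
#' half-cycle correction (trapezoid on adjacent-cycle state membership);
#' QALY increments additionally weight by the cycle's utility
#' ([postdischarge_utility()]) and the discount factor `(1+r)^(-t/12)`, with
#' `t` in months measured from model entry (the acute phase occupies months
#' `0 .. acute_phase_cycles - 1`). The trace ends at the horizon age or when
#' the surviving fraction falls below `1e-12`.
#'
#' @param discharge_age Age in years at hospital discharge.
#' @param lt A [life_table].
#' @param utilities,settings Components of [cea_parameters].
#' @return A `cohort_trace` data frame with one row per cycle: `cycle`,
#'   `age`, `alive`, `utility`, `discount`, `ly_inc`, `ly_disc_inc`,
#'   `qaly_inc`.
#' @export
run_cohort <- function(discharge_age, lt, utilities, settings) {
  z <- .cohort_core(discharge_age, lt, utilities, settings)
  tr <- data.frame(
    cycle = z$cycle,
    age = z$age,
    alive = z$alive,
    utility = z$utility,
    discount = z$discount,
    ly_inc = z$ly_inc,
    ly_disc_inc = z$ly_inc * z$discount,
    qaly_inc = z$ly_inc * z$utility * z$discount
  )
  class(tr) <- c("cohort_trace", "data.frame")
  tr
}

#' Aggregate a cohort trace
#'
#' @param trace A `cohort_trace` from [run_cohort()].
#' @return Named list: `ly` (undiscounted life years), `ly_discounted`, and
#'   `qaly_discounted`, all per surviving patient entering the cohort.
#' @export
discounted_survivor_totals <- function(trace) {
  stopifnot(is.data.frame(trace),
            all(c("ly_inc", "ly_disc_inc", "qaly_inc") %in% names(trace)))
  list(ly = sum(trace$ly_inc),
       ly_discounted = sum(trace$ly_disc_inc),
       qaly_discounted = sum(trace$qaly_inc))
}

# Fast path used by the PSA: totals only, no data frame.
.cohort_totals <- function(discharge_age, lt, utilities, settings) {
  z <- .cohort_core(discharge_age, lt, utilities, settings)
  ld <- z$ly_inc * z$discount
  list(ly = sum(z$ly_inc), ly_discounted = sum(ld),
       qaly_discounted = sum(ld * z$utility))
}

#' @export
print.cohort_trace <- function(x, ...) {
  cat(sprintf("<cohort_trace> %d monthly cycles, ages %.2f-%.2f\n",
              nrow(x), x$age[1], x$age[nrow(x)]))
  t <- discounted_survivor_totals(x)
  cat(sprintf("  LY %.4f (undiscounted), %.4f (discounted); QALY %.4f (discounted)\n",
              t$ly, t$ly_discounted, t$qaly_discounted))
  invisible(x)
}
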