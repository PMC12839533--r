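#' Equal-value life years
#'
#' Values discounted life years at a fixed reference utility, so that
#' survival gains are not discounted for the quality of life in which they
#' are lived: `evly = reference_utility * ly_discounted`. On the incremental
#' scale this equals the equal-value-of-life-years-gained (evLYG) statistic.
#'
#' @param ly_discounted Discounted life years (acute + post-discharge).
#' @param reference_utility Reference utility in (0, 1\].
#' @return Equal-value life years.
#' @export
evly_from <- function(ly_discounted, reference_utility) {
  if (ly_discounted < 0) stop("evly_from(): negative life years")
  if (reference_utility <= 0 || reference_utility > 1) {
    stop("evly_from(): reference utility must be in (0,1]")
  }
  reference_utility * ly_discounted
}

#' Combine acute and post-discharge stages into per-arm totals
#'
#' Total cost is the acute-phase expected cost (no post-discharge healthcare
#' costs are accrued). Life years and QALYs add the acute contribution to the
#' survivor fraction times the per-survivor cohort totals. Life years are
#' reported undiscounted; QALYs and equal-value life years discounted.
#'
#' @param acute An `acute_outcome` from [acute_phase_outcomes()].
#' @param trace A `cohort_trace` from [run_cohort()] (or its
#'   [discounted_survivor_totals()]).
#' @param evly_reference_utility Reference utility for [evly_from()].
#' @return An `arm_results` list: `strategy`, `total_cost`, `ly`,
#'   `ly_discounted`, `qaly`, `evly`.
#' @export
arm_results <- function(acute, trace, evly_reference_utility = 0.851) {
  tot <- if (is.data.frame(trace)) discounted_survivor_totals(trace) else trace
  s <- acute$survivor_fraction
  lyd <- acute$acute_ly_discounted + s * tot$ly_discounted
  out <- list(
    strategy = acute$strategy,
    total_cost = acute$expected_cost,
    ly = acute$acute_ly + s * tot$ly,
    ly_discounted = lyd,
    qaly = acute$acute_qaly + s * tot$qaly_discounted,
    evly = evly_from(lyd, evly_reference_utility)
  )
  class(out) <- "arm_results"
  out
}

#' Incremental cost-effectiveness statistics
#'
#' Deltas are computed on unrounded totals (intervention minus reference).
#' The ICER is reported only when the signs admit a meaningful ratio; a
#' strategy that is cheaper and more effective is `"dominant"`, one that is
#' costlier and less effective is `"dominated"`. A negligible QALY difference
#' with a real cost difference yields an undefined ICER.
#'
#' @param reference,intervention `arm_results` for the two strategies.
#' @return A `ce_result` list: `reference`, `intervention`, `delta_cost`,
#'   `delta_qaly`, `delta_ly`, `delta_ly_discounted`, `evlyg`, `icer`
#'   (numeric, or `NA` when flagged), `dominance` (`"dominant"`,
#'   `"dominated"`, `"undefined"` or `NA`).
#' @export
compute_icer <- function(reference, intervention) {
  if (identical(reference$strategy, intervention$strategy)) {
    stop("compute_icer(): the two strategies must be distinct")
  }
  dc <- intervention$total_cost - reference$total_cost
  dq <- intervention$qaly - reference$qaly
  dominance <- NA_character_
  icer <- NA_real_
  if (abs(dq) < 1e-12) {
    dominance <- "undefined"
  } else if (dc <= 0 && dq > 0) {
    dominance <- "dominant"
  } else if (dc >= 0 && dq < 0) {
    dominance <- "dominated"
  } else {
    icer <- dc / dq
  }
  out <- list(
    reference = reference$strategy,
    intervention = intervention$strategy,
    delta_cost = dc,
    delta_qaly = dq,
    delta_ly = intervention$ly - reference$ly,
    delta_ly_discounted = intervention$ly_discounted - reference$ly_discounted,
    evlyg = intervention$evly - reference$evly,
    icer = icer,
    dominance = dominance
  )
  class(out) <- "ce_result"
  out
}

#' Net monetary benefit
#'
#' @param delta_cost Incremental cost (USD).
#' @param delta_qaly Incremental QALYs.
#' @param wtp Willingness-to-pay threshold (USD/QALY), nonnegative.
#' @return `wtp * delta_qaly - delta_cost`, in USD.
#' @export
net_monetary_benefit <- function(delta_cost, delta_qaly, wtp) {
  if (any(wtp < 0)) stop("net_monetary_benefit(): negative WTP")
  wtp * delta_qaly - delta_cost
}

#' Run the full base-case model
#'
#' Evaluates the acute-care decision tree for both arms, runs the shared
#' post-discharge Markov cohort (the discharge age and utility schedule do
#' not differ by arm), and combines them into per-arm totals and incremental
#' statistics.
#'
#' @param params A [cea_parameters] object.
#' @param lt A [life_table].
#' @return A `cea_run` list: `arms` (list of `arm_results`, reference first),
#'   `incremental` (a `ce_result`), `nmb_at_wtp`, and the per-survivor
#'   cohort `totals`.
#' @export
run_cea <- function(params, lt) {
  st <- params$settings
  names_arms <- names(params$arms)
  acute <- lapply(names_arms, function(nm) {
    acute_phase_outcomes(params$arms[[nm]], params$costs, params$utilities,
                         st, strategy = nm)
  })
  tot <- .cohort_totals(acute[[1]]$discharge_age, lt, params$utilities, st)
  arms <- lapply(acute, arm_results, trace = tot,
                 evly_reference_utility = st$evly_reference_utility)
  names(arms) <- names_arms
  inc <- compute_icer(arms[[1]], arms[[2]])
  out <- list(
    arms = arms,
    incremental = inc,
    nmb_at_wtp = net_monetary_benefit(inc$delta_cost, inc$delta_qaly,
                                      st$wtp_threshold),
    totals = tot
  )
  class(out) <- "cea_run"
  out
}

#' Tabulate a base-case run
#'
#' One row per strategy in full precision, mirroring the usual base-case
#' results table: cost, incremental cost, QALYs, incremental QALYs, ICER
#' (plus life years and equal-value life years).
#'
#' @param run A `cea_run` from [run_cea()].
#' @return A data frame with one row per strategy.
#' @export
results_table <- function(run) {
  ref <- run$arms[[1]]
  int <- run$arms[[2]]
  inc <- run$incremental
  data.frame(
    strategy = c(ref$strategy, int$strategy),
    cost = c(ref$total_cost, int$total_cost),
    incremental_cost = c(NA_real_, inc$delta_cost),
    ly = c(ref$ly, int$ly),
    qaly = c(ref$qaly, int$qaly),
    incremental_qaly = c(NA_real_, inc$delta_qaly),
    evly = c(ref$evly, int$evly),
    icer = c(NA_real_, inc$icer),
    stringsAsFactors = FALSE
  )
}

#' @export
print.cea_run <- function(x, ...) {
  tab <- results_table(x)
  cat("<cea_run>", tab$strategy[2], "vs", tab$strategy[1], "\n")
  fmt <- function(v, d = 2) formatC(v, format = "f", digits = d,
                                    big.mark = ",")
  for (i in 1:2) {
    cat(sprintf("  %-12s cost $%s  LY %s  QALY %s  evLY %s\n",
                tab$strategy[i], fmt(tab$cost[i]), fmt(tab$ly[i]),
                fmt(tab$qaly[i]), fmt(tab$evly[i])))
  }
  inc <- x$incremental
  if (!is.na(inc$icer)) {
    cat(sprintf("  incremental: $%s for %s QALYs -> ICER $%s/QALY\n",
                fmt(inc$delta_cost), fmt(inc$delta_qaly, 4),
                fmt(inc$icer, 0)))
  } else {
    cat("  incremental:", inc$dominance, "\n")
  }
  invisible(x)
}
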