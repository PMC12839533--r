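#' One-way deterministic sensitivity analysis
#'
#' For each parameter path, re-runs the full base-case model with that
#' parameter at the low and at the high end of its uncertainty range, holding
#' everything else at base. Results are sorted by descending ICER span
#' (tornado order); ties break alphabetically by path.
#'
#' @param params A [cea_parameters] object.
#' @param lt A [life_table].
#' @param paths Character vector of parameter paths to vary; default: every
#'   uncertainty specification that carries a low/high range.
#' @return A `dsa_results` data frame: `parameter`, `low_value`,
#'   `base_value`, `high_value`, `icer_at_low`, `icer_at_high`, `direction`
#'   (`"increase"` if the ICER rises with the parameter), `span`.
#' @export
one_way_dsa <- function(params, lt, paths = NULL) {
  specs <- params$uncertainty
  names(specs) <- vapply(specs, `[[`, character(1), "path")
  if (is.null(paths)) {
    has_range <- vapply(specs, function(s) {
      !is.null(s$low) && !is.null(s$high)
    }, TRUE)
    paths <- names(specs)[has_range]
  }
  if (length(paths) == 0L) stop("one_way_dsa(): no parameters to vary")

  icer_of <- function(p) run_cea(p, lt)$incremental$icer
  rows <- lapply(paths, function(pp) {
    sp <- specs[[pp]]
    if (is.null(sp) || is.null(sp$low) || is.null(sp$high)) {
      stop("one_way_dsa(): no low/high range for parameter '", pp, "'")
    }
    base <- get_param(params, pp)
    lo <- icer_of(set_param(params, pp, sp$low))
    hi <- icer_of(set_param(params, pp, sp$high))
    data.frame(parameter = pp, low_value = sp$low, base_value = base,
               high_value = sp$high, icer_at_low = lo, icer_at_high = hi,
               direction = if (isTRUE(hi >= lo)) "increase" else "decrease",
               span = abs(hi - lo), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res <- res[order(-res$span, res$parameter), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("dsa_results", "data.frame")
  res
}

#' Top rows of a tornado analysis
#'
#' @param results A `dsa_results` data frame from [one_way_dsa()].
#' @param top_k Number of rows to keep (by descending span).
#' @return The first `top_k` rows; if fewer are available, all rows with a
#'   message.
#' @export
tornado_table <- function(results, top_k = 3L) {
  stopifnot(is.data.frame(results))
  if (top_k < 0) stop("tornado_table(): top_k must be nonnegative")
  if (top_k > nrow(results)) {
    message("tornado_table(): only ", nrow(results),
            " parameters available (requested ", top_k, ")")
    top_k <- nrow(results)
  }
  out <- utils::head(results, top_k)
  rownames(out) <- NULL
  out
}

#' Probabilistic sensitivity analysis
#'
#' Draws every distributed parameter independently from its fitted
#' distribution (beta and gamma by method of moments from the printed mean
#' and 95% range or SD; age truncated-normal by resampling), re-runs the full
#' model per draw, and records incremental cost and QALYs. Parameters whose
#' specification is `fixed` (the unit costs) stay at base. Parameters are
#' sampled in the order they appear in `params$uncertainty`, one block per
#' parameter, from a single seeded generator, so identical `(seed, n)` give
#' identical draws.
#'
#' @param params A [cea_parameters] object.
#' @param lt A [life_table].
#' @param n Number of draws.
#' @param seed Integer seed.
#' @return A `psa_draws` object: `n`, `seed`, `draws` (data frame with one
#'   row per draw: sampled parameters, `delta_cost`, `delta_qaly`,
#'   `icer`), and `sampled_paths`.
#' @export
sample_psa <- function(params, lt,
                       n = params$settings$n_psa_draws,
                       seed = params$settings$rng_seed) {
  stopifnot(n >= 1)
  specs <- params$uncertainty
  sampled <- Filter(function(s) s$family != "fixed", specs)
  # fit all distributions up front: an infeasible spec fails before any draw
  samplers <- lapply(sampled, function(s) {
    .make_sampler(s, get_param(params, s$path))
  })
  paths <- vapply(sampled, `[[`, character(1), "path")

  set.seed(seed)
  mat <- matrix(0, nrow = n, ncol = length(sampled),
                dimnames = list(NULL, paths))
  for (j in seq_along(samplers)) mat[, j] <- samplers[[j]](n)

  dc <- dq <- numeric(n)
  for (i in seq_len(n)) {
    p <- params
    for (j in seq_along(paths)) p <- set_param(p, paths[j], mat[i, j])
    run <- run_cea(p, lt)
    dc[i] <- run$incremental$delta_cost
    dq[i] <- run$incremental$delta_qaly
  }
  draws <- as.data.frame(mat)
  draws$delta_cost <- dc
  draws$delta_qaly <- dq
  draws$icer <- ifelse(abs(dq) < 1e-12, NA_real_, dc / dq)
  out <- list(n = n, seed = seed, draws = draws, sampled_paths = paths)
  class(out) <- "psa_draws"
  out
}

#' Cost-effectiveness acceptability curve
#'
#' Fraction of PSA draws with strictly positive net monetary benefit at each
#' willingness-to-pay value (ties at zero count as not accepted).
#'
#' @param psa A `psa_draws` object from [sample_psa()].
#' @param wtp_grid Willingness-to-pay grid in USD/QALY.
#' @return Data frame with columns `wtp` and `fraction_accepted`.
#' @export
ceac <- function(psa, wtp_grid = seq(0, 150000, by = 1000)) {
  stopifnot(length(wtp_grid) >= 1L)
  d <- psa$draws
  if (nrow(d) == 0L) stop("ceac(): no draws")
  frac <- vapply(wtp_grid, function(w) {
    mean(net_monetary_benefit(d$delta_cost, d$delta_qaly, w) > 0)
  }, numeric(1))
  data.frame(wtp = wtp_grid, fraction_accepted = frac)
}

#' @export
print.psa_draws <- function(x, ...) {
  cat(sprintf("<psa_draws> %d draws (seed %d), %d sampled parameters\n",
              x$n, x$seed, length(x$sampled_paths)))
  cat(sprintf("  mean incremental cost $%s, mean incremental QALY %.3f\n",
              format(round(mean(x$draws$delta_cost)), big.mark = ","),
              mean(x$draws$delta_qaly)))
  invisible(x)
}
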