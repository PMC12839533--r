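#' @title Model parameters
#' @description
#' A `cea_parameters` object holds every input of the analysis: per-arm
#' clinical parameters, unit costs, the utility schedule, analysis settings,
#' and the uncertainty specifications used by the deterministic and
#' probabilistic sensitivity analyses. The first arm in `arms` is the
#' reference strategy, the second the intervention.
#' @name cea_parameters
NULL

# Allowed keys per level; anything else is rejected by validation.
.schema <- list(
  top       = c("arms", "costs", "utilities", "settings", "uncertainty"),
  arm       = c("survival_60d", "p_rrt", "rrt_days", "n_drug_administrations"),
  costs     = c("icu_cost", "rrt_cost_per_day", "drug_cost_per_admin"),
  utilities = c("age_band_utilities", "mv_disutility",
                "postdischarge_disutility_by_year"),
  band      = c("min", "max", "utility"),
  settings  = c("start_age", "acute_phase_cycles", "annual_discount_rate",
                "horizon_age", "wtp_threshold", "evly_reference_utility",
                "n_psa_draws", "rng_seed"),
  spec      = c("path", "family", "low", "high", "sd")
)

#' Default model parameters
#'
#' Returns the base-case parameter set for the vilobelimab vs standard-of-care
#' comparison in mechanically ventilated COVID-19 patients receiving
#' immunomodulators: 60-day survival 0.82 vs 0.51, renal replacement therapy
#' probabilities 0.096 vs 0.157 with mean durations 6.8 and 9.4 days, ICU cost
#' $100,461, RRT $2,000/day, drug cost $6,350 per administration with a mean
#' of 4.8 administrations, the age-specific utility schedule with a 0.56
#' in-hospital mechanical-ventilation disutility and four years of
#' post-discharge disutility, cohort entry at age 58.6, a 3%/year discount
#' rate, and a lifetime horizon (age 100).
#'
#' Uncertainty specifications mirror the published parameter table: beta
#' distributions for probabilities and utilities, gamma for durations, a
#' truncated normal for age, and fixed (range-only) costs. The intervention
#' arm's RRT duration uses a symmetric 5.8-7.8 day range; see the methods
#' vignette for why the published range for that entry is not usable as-is.
#'
#' @return A validated `cea_parameters` object.
#' @export
default_parameters <- function() {
  p <- list(
    arms = list(
      soc = list(
        survival_60d = 0.51,
        p_rrt = 0.157,
        rrt_days = 9.4,
        n_drug_administrations = 0
      ),
      vilobelimab = list(
        survival_60d = 0.82,
        p_rrt = 0.096,
        rrt_days = 6.8,
        n_drug_administrations = 4.8
      )
    ),
    costs = list(
      icu_cost = 100461,
      rrt_cost_per_day = 2000,
      drug_cost_per_admin = 6350
    ),
    utilities = list(
      age_band_utilities = list(
        list(min = 0,  max = 50,  utility = 0.870),
        list(min = 50, max = 60,  utility = 0.840),
        list(min = 60, max = 70,  utility = 0.820),
        list(min = 70, max = 80,  utility = 0.790),
        list(min = 80, max = 200, utility = 0.740)
      ),
      mv_disutility = 0.560,
      postdischarge_disutility_by_year = c(0.130, 0.067, 0.062, 0.026)
    ),
    settings = list(
      start_age = 58.6,
      acute_phase_cycles = 2,
      annual_discount_rate = 0.03,
      horizon_age = 100,
      wtp_threshold = 50000,
      evly_reference_utility = 0.851,
      n_psa_draws = 10000,
      rng_seed = 1234
    ),
    uncertainty = list(
      list(path = "arms.vilobelimab.survival_60d", family = "beta",
           low = 0.65, high = 0.93),
      list(path = "arms.soc.survival_60d", family = "beta",
           low = 0.34, high = 0.66),
      list(path = "settings.start_age", family = "normal",
           low = 22, high = 79),
      list(path = "arms.vilobelimab.p_rrt", family = "beta",
           low = 0.086, high = 0.106),
      list(path = "arms.soc.p_rrt", family = "beta",
           low = 0.141, high = 0.173),
      list(path = "arms.vilobelimab.rrt_days", family = "gamma",
           low = 5.8, high = 7.8),
      list(path = "arms.soc.rrt_days", family = "gamma",
           low = 8.1, high = 10.7),
      list(path = "costs.rrt_cost_per_day", family = "fixed",
           low = 1800, high = 2200),
      list(path = "costs.drug_cost_per_admin", family = "fixed",
           low = 5715, high = 6985),
      list(path = "costs.icu_cost", family = "fixed",
           low = 40218, high = 100461),
      list(path = "utilities.age_band_utilities.1.utility", family = "beta",
           sd = 0.002),
      list(path = "utilities.age_band_utilities.2.utility", family = "beta",
           sd = 0.003),
      list(path = "utilities.age_band_utilities.3.utility", family = "beta",
           sd = 0.003),
      list(path = "utilities.age_band_utilities.4.utility", family = "beta",
           sd = 0.004),
      list(path = "utilities.age_band_utilities.5.utility", family = "beta",
           sd = 0.006),
      list(path = "utilities.mv_disutility", family = "beta", sd = 0.300),
      list(path = "utilities.postdischarge_disutility_by_year.1",
           family = "beta", sd = 0.013),
      list(path = "utilities.postdischarge_disutility_by_year.2",
           family = "beta", sd = 0.007),
      list(path = "utilities.postdischarge_disutility_by_year.3",
           family = "beta", sd = 0.006),
      list(path = "utilities.postdischarge_disutility_by_year.4",
           family = "beta", sd = 0.001)
    )
  )
  structure(p, class = "cea_parameters")
}

#' Read or write a parameter by dotted path
#'
#' Paths address scalars inside a `cea_parameters` object, e.g.
#' `"arms.vilobelimab.survival_60d"`, `"settings.start_age"`, or
#' `"utilities.age_band_utilities.2.utility"` (numeric segments index into
#' lists and vectors). These are the paths used by the uncertainty
#' specifications, the one-way sensitivity analysis, and the PSA.
#'
#' @param params A `cea_parameters` object (any nested list works).
#' @param path Dotted path string.
#' @param value Replacement scalar for `set_param()`.
#' @return `get_param()` the addressed scalar; `set_param()` the modified
#'   object.
#' @export
get_param <- function(params, path) {
  segs <- strsplit(path, ".", fixed = TRUE)[[1]]
  node <- params
  for (s in segs) {
    idx <- if (grepl("^[0-9]+$", s)) as.integer(s) else s
    if (is.character(idx) && (is.null(node[[idx]]) && !idx %in% names(node))) {
      stop("parameter path not found: '", path, "' (missing '", s, "')")
    }
    if (is.numeric(idx) && idx > length(node)) {
      stop("parameter path not found: '", path, "' (index ", s,
           " out of bounds)")
    }
    node <- node[[idx]]
  }
  node
}

#' @rdname get_param
#' @export
set_param <- function(params, path, value) {
  segs <- strsplit(path, ".", fixed = TRUE)[[1]]
  get_param(params, path)  # bounds / existence check
  idx <- lapply(segs, function(s) {
    if (grepl("^[0-9]+$", s)) as.integer(s) else s
  })
  rec <- function(node, i) {
    if (i > length(idx)) return(value)
    node[[idx[[i]]]] <- rec(node[[idx[[i]]]], i + 1L)
    node
  }
  rec(params, 1L)
}

.check_keys <- function(x, allowed, where, fail) {
  extra <- setdiff(names(x), allowed)
  for (k in extra) fail(sprintf("unknown key '%s' in %s", k, where))
  missing <- setdiff(allowed, names(x))
  for (k in missing) fail(sprintf("missing key '%s' in %s", k, where))
}

.is_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

#' Validate a parameter set
#'
#' Checks structure (unknown or missing keys are rejected by name), types,
#' and all domain invariants: probabilities in \[0,1\], nonnegative costs and
#' durations, utilities in \[0,1\] with contiguous closed-open age bands,
#' exactly four post-discharge disutility entries, coherent analysis settings,
#' and resolvable uncertainty paths with `low <= base <= high`.
#'
#' All failures are collected and reported together.
#'
#' @param params Candidate parameter list.
#' @param on_inverted_range What to do when an uncertainty range does not
#'   bracket its base value: `"fix"` replaces it by a symmetric range of the
#'   same width centred on the base (with a warning), `"keep"` accepts it
#'   as printed, `"error"` fails validation.
#' @return The validated (possibly range-corrected) `cea_parameters` object,
#'   invisibly classed.
#' @export
validate_parameters <- function(params,
                                on_inverted_range = c("fix", "keep", "error")) {
  on_inverted_range <- match.arg(on_inverted_range)
  errs <- character()
  fail <- function(msg) errs <<- c(errs, msg)

  .check_keys(params, .schema$top, "parameters", fail)

  arms <- params$arms
  if (!is.list(arms) || length(arms) != 2L || is.null(names(arms)) ||
      any(names(arms) == "")) {
    fail("arms: exactly two named strategies are required (reference first)")
  } else {
    for (nm in names(arms)) {
      a <- arms[[nm]]
      .check_keys(a, .schema$arm, paste0("arms.", nm), fail)
      for (k in intersect(names(a), .schema$arm)) {
        if (!.is_num(a[[k]])) fail(sprintf("arms.%s.%s: not a number", nm, k))
      }
      if (.is_num(a$survival_60d) &&
          (a$survival_60d < 0 || a$survival_60d > 1)) {
        fail(sprintf("arms.%s.survival_60d: probability outside [0,1] (%s)",
                     nm, a$survival_60d))
      }
      if (.is_num(a$p_rrt) && (a$p_rrt < 0 || a$p_rrt > 1)) {
        fail(sprintf("arms.%s.p_rrt: probability outside [0,1] (%s)",
                     nm, a$p_rrt))
      }
      if (.is_num(a$rrt_days) && a$rrt_days < 0) {
        fail(sprintf("arms.%s.rrt_days: negative duration", nm))
      }
      if (.is_num(a$n_drug_administrations) && a$n_drug_administrations < 0) {
        fail(sprintf("arms.%s.n_drug_administrations: negative count", nm))
      }
    }
  }

  costs <- params$costs
  if (is.list(costs)) {
    .check_keys(costs, .schema$costs, "costs", fail)
    for (k in intersect(names(costs), .schema$costs)) {
      if (!.is_num(costs[[k]])) {
        fail(sprintf("costs.%s: not a number", k))
      } else if (costs[[k]] < 0) {
        fail(sprintf("costs.%s: negative cost", k))
      }
    }
  } else fail("costs: missing or not a mapping")

  u <- params$utilities
  if (is.list(u)) {
    .check_keys(u, .schema$utilities, "utilities", fail)
    bands <- u$age_band_utilities
    if (!is.list(bands) || length(bands) < 1L) {
      fail("utilities.age_band_utilities: at least one age band required")
    } else {
      prev_max <- NULL
      for (i in seq_along(bands)) {
        b <- bands[[i]]
        .check_keys(b, .schema$band,
                    sprintf("utilities.age_band_utilities.%d", i), fail)
        if (all(vapply(b[.schema$band], .is_num, TRUE))) {
          if (b$min >= b$max) {
            fail(sprintf("utilities.age_band_utilities.%d: min >= max", i))
          }
          if (b$utility < 0 || b$utility > 1) {
            fail(sprintf(
              "utilities.age_band_utilities.%d.utility: outside [0,1]", i))
          }
          if (!is.null(prev_max) && !isTRUE(all.equal(prev_max, b$min))) {
            fail(sprintf(
              "utilities.age_band_utilities.%d: bands not contiguous", i))
          }
          prev_max <- b$max
        }
      }
    }
    if (!.is_num(u$mv_disutility) || u$mv_disutility < 0) {
      fail("utilities.mv_disutility: must be a nonnegative number")
    }
    pd <- u$postdischarge_disutility_by_year
    if (!is.numeric(pd) || length(pd) != 4L) {
      fail("utilities.postdischarge_disutility_by_year: exactly 4 entries required")
    } else if (any(pd < 0)) {
      fail("utilities.postdischarge_disutility_by_year: negative decrement")
    }
  } else fail("utilities: missing or not a mapping")

  s <- params$settings
  if (is.list(s)) {
    .check_keys(s, .schema$settings, "settings", fail)
    for (k in intersect(names(s), .schema$settings)) {
      if (!.is_num(s[[k]])) fail(sprintf("settings.%s: not a number", k))
    }
    if (.is_num(s$start_age) && .is_num(s$horizon_age) &&
        !(s$start_age > 0 && s$start_age < s$horizon_age)) {
      fail("settings: need 0 < start_age < horizon_age")
    }
    if (.is_num(s$annual_discount_rate) && s$annual_discount_rate < 0) {
      fail("settings.annual_discount_rate: negative rate")
    }
    if (.is_num(s$acute_phase_cycles) && s$acute_phase_cycles < 1) {
      fail("settings.acute_phase_cycles: at least one monthly cycle")
    }
    if (.is_num(s$n_psa_draws) && s$n_psa_draws < 1) {
      fail("settings.n_psa_draws: at least one draw")
    }
    if (.is_num(s$evly_reference_utility) &&
        (s$evly_reference_utility <= 0 || s$evly_reference_utility > 1)) {
      fail("settings.evly_reference_utility: must be in (0,1]")
    }
  } else fail("settings: missing or not a mapping")

  unc <- params$uncertainty
  if (!is.null(unc)) {
    if (!is.list(unc)) fail("uncertainty: must be a list of specifications")
    for (i in seq_along(unc)) {
      sp <- unc[[i]]
      where <- sprintf("uncertainty[%d]", i)
      extra <- setdiff(names(sp), .schema$spec)
      for (k in extra) fail(sprintf("unknown key '%s' in %s", k, where))
      if (is.null(sp$path) || is.null(sp$family)) {
        fail(paste0(where, ": 'path' and 'family' are required"))
        next
      }
      if (!sp$family %in% c("beta", "gamma", "normal", "fixed")) {
        fail(sprintf("%s (%s): unknown family '%s'", where, sp$path,
                     sp$family))
        next
      }
      base <- tryCatch(get_param(params, sp$path), error = function(e) NULL)
      if (is.null(base) || !.is_num(base)) {
        fail(sprintf("%s: path '%s' does not resolve to a scalar parameter",
                     where, sp$path))
        next
      }
      has_range <- !is.null(sp$low) && !is.null(sp$high)
      if (!has_range && is.null(sp$sd) && sp$family != "fixed") {
        fail(sprintf("%s (%s): needs a low/high range or an sd", where,
                     sp$path))
      }
      if (has_range && sp$family != "fixed" &&
          (base < sp$low || base > sp$high)) {
        if (on_inverted_range == "error") {
          fail(sprintf(
            "%s (%s): base %s outside range [%s, %s]", where, sp$path,
            base, sp$low, sp$high))
        } else if (on_inverted_range == "fix") {
          half <- (sp$high - sp$low) / 2
          warning(sprintf(
            paste0("uncertainty range for '%s' does not bracket its base ",
                   "value %s; substituting symmetric range [%s, %s]"),
            sp$path, base, base - half, base + half), call. = FALSE)
          unc[[i]]$low <- base - half
          unc[[i]]$high <- base + half
        }
      }
      if (sp$family == "beta" && (base <= 0 || base >= 1)) {
        fail(sprintf("%s (%s): beta requires base in (0,1)", where, sp$path))
      }
      if (sp$family == "gamma" && base <= 0) {
        fail(sprintf("%s (%s): gamma requires base > 0", where, sp$path))
      }
    }
    params$uncertainty <- unc
  }

  if (length(errs) > 0L) {
    stop("invalid parameters:\n  - ", paste(errs, collapse = "\n  - "),
         call. = FALSE)
  }
  structure(params, class = "cea_parameters")
}

#' Load model parameters from a YAML configuration file
#'
#' @param path Path to a YAML document with top-level keys `arms`, `costs`,
#'   `utilities`, `settings` and `uncertainty`. The bundled default is at
#'   `system.file("extdata", "default_config.yaml", package = "vilocea")`.
#' @inheritParams validate_parameters
#' @return A validated `cea_parameters` object.
#' @export
load_parameters <- function(path, on_inverted_range = c("fix", "keep", "error")) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$utilities$postdischarge_disutility_by_year)) {
    raw$utilities$postdischarge_disutility_by_year <-
      as.numeric(unlist(raw$utilities$postdischarge_disutility_by_year))
  }
  validate_parameters(raw, on_inverted_range = on_inverted_range)
}

#' Save model parameters to a YAML configuration file
#'
#' Writes the full parameter set; `load_parameters()` on the result returns
#' an equal object (round-trip identity up to floating-point formatting).
#'
#' @param params A `cea_parameters` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_parameters <- function(params, path) {
  params <- validate_parameters(unclass(params), on_inverted_range = "keep")
  txt <- yaml::as.yaml(unclass(params), precision = 15L)
  writeLines(txt, path)
  invisible(path)
}

#' Path to the bundled default configuration
#' @return File path of the installed default YAML configuration.
#' @export
default_config_path <- function() {
  system.file("extdata", "default_config.yaml", package = "vilocea",
              mustWork = TRUE)
}

#' Path to the bundled synthetic life table
#' @return File path of the installed synthetic US-like life table.
#' @export
default_life_table_path <- function() {
  system.file("extdata", "lifetable_us_synthetic.tsv", package = "vilocea",
              mustWork = TRUE)
}

#' @export
print.cea_parameters <- function(x, ...) {
  s <- x$settings
  cat("<cea_parameters>\n")
  cat("  strategies:", paste(names(x$arms), collapse = " vs "),
      "(reference first)\n")
  for (nm in names(x$arms)) {
    a <- x$arms[[nm]]
    cat(sprintf("    %-12s 60-day survival %.3f, P(RRT) %.3f over %.1f d, %.1f drug administrations\n",
                nm, a$survival_60d, a$p_rrt, a$rrt_days,
                a$n_drug_administrations))
  }
  cat(sprintf("  entry age %.1f y, horizon age %s y, discount %.1f%%/y, WTP $%s/QALY\n",
              s$start_age, s$horizon_age, 100 * s$annual_discount_rate,
              format(s$wtp_threshold, big.mark = ",")))
  cat(sprintf("  %d uncertainty specifications (%d sampled in PSA)\n",
              length(x$uncertainty),
              sum(vapply(x$uncertainty,
                         function(u) u$family != "fixed", TRUE))))
  invisible(x)
}
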