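# Reporting layer: each entry point loads inputs, runs the analysis, writes
# canonical CSVs in full precision plus a JSON manifest, and returns the
# in-memory results invisibly. Rounding happens only in printed summaries.

.write_manifest <- function(command, config_path, seed, out_dir, outputs) {
  manifest <- list(
    command = command,
    config_digest = unname(tools::md5sum(config_path)),
    seed = seed,
    package_version = as.character(utils::packageVersion("vilocea")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    outputs = outputs
  )
  path <- file.path(out_dir, paste0(command, "_manifest.json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  for (f in outputs) {
    if (!file.exists(f)) stop("manifest lists a missing output: ", f)
  }
  invisible(path)
}

.load_inputs <- function(config_path, life_table_path) {
  if (!file.exists(config_path)) {
    stop("configuration file not found: ", config_path)
  }
  if (!file.exists(life_table_path)) {
    stop("life table file not found: ", life_table_path)
  }
  list(params = load_parameters(config_path),
       lt = read_life_table(life_table_path))
}

#' Run the base-case analysis and write its results table
#'
#' Writes `base_case.csv` (one row per strategy: cost, incremental cost,
#' life years, QALYs, incremental QALYs, evLY, ICER, in full precision) and
#' a JSON manifest recording the config digest, seed, package version and
#' output paths.
#'
#' @param config_path YAML configuration ([load_parameters()]).
#' @param life_table_path Life-table file ([read_life_table()]).
#' @param out_dir Output directory (created if missing).
#' @return The `cea_run`, invisibly.
#' @export
run_base <- function(config_path = default_config_path(),
                     life_table_path = default_life_table_path(),
                     out_dir = ".") {
  inp <- .load_inputs(config_path, life_table_path)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  run <- run_cea(inp$params, inp$lt)
  out <- file.path(out_dir, "base_case.csv")
  utils::write.csv(results_table(run), out, row.names = FALSE)
  .write_manifest("run_base", config_path, inp$params$settings$rng_seed,
                  out_dir, out)
  message(sprintf("base case: incremental cost $%s, incremental QALY %.4f, ICER $%s/QALY",
                  format(round(run$incremental$delta_cost), big.mark = ","),
                  run$incremental$delta_qaly,
                  format(round(run$incremental$icer), big.mark = ",")))
  invisible(run)
}

#' Run the one-way sensitivity analysis and write the tornado table
#'
#' Writes `tornado.csv` ordered by descending ICER span, optionally a
#' tornado plot, plus a manifest.
#'
#' @inheritParams run_base
#' @param top Keep only the `top` widest parameters (default: all).
#' @param plot Also write `tornado.pdf` (requires ggplot2).
#' @return The `dsa_results`, invisibly.
#' @export
run_dsa <- function(config_path = default_config_path(),
                    life_table_path = default_life_table_path(),
                    out_dir = ".", top = NULL, plot = FALSE) {
  inp <- .load_inputs(config_path, life_table_path)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- one_way_dsa(inp$params, inp$lt)
  if (!is.null(top)) res <- tornado_table(res, top)
  out <- file.path(out_dir, "tornado.csv")
  utils::write.csv(res, out, row.names = FALSE)
  outputs <- out
  if (isTRUE(plot)) {
    pfile <- file.path(out_dir, "tornado.pdf")
    .save_plot(plot_tornado(res), pfile)
    outputs <- c(outputs, pfile)
  }
  .write_manifest("run_dsa", config_path, inp$params$settings$rng_seed,
                  out_dir, outputs)
  message("one-way DSA: widest parameter is '", res$parameter[1],
          "' (ICER span $", format(round(res$span[1]), big.mark = ","), ")")
  invisible(res)
}

#' Run the probabilistic sensitivity analysis and write draws and CEAC
#'
#' Writes `psa_draws.csv` (per-draw sampled parameters and incremental
#' results), `ceac.csv` (acceptance fraction over the WTP grid), optional
#' scatter and CEAC plots, plus a manifest. The acceptance fraction at the
#' configured willingness-to-pay threshold is echoed as a message.
#'
#' @inheritParams run_base
#' @param n Number of draws (default from the configuration).
#' @param seed Integer seed (default from the configuration).
#' @param wtp_grid Willingness-to-pay grid for the CEAC.
#' @param plot Also write `psa_scatter.pdf` and `ceac.pdf` (requires
#'   ggplot2).
#' @return List with the `psa_draws` and the CEAC data frame, invisibly.
#' @export
run_psa <- function(config_path = default_config_path(),
                    life_table_path = default_life_table_path(),
                    out_dir = ".", n = NULL, seed = NULL,
                    wtp_grid = seq(0, 150000, by = 1000), plot = FALSE) {
  inp <- .load_inputs(config_path, life_table_path)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  st <- inp$params$settings
  if (is.null(n)) n <- st$n_psa_draws
  if (is.null(seed)) seed <- st$rng_seed
  if (n < 1) stop("run_psa(): need at least one draw (--n-draws)")
  if (n < 10000) {
    warning("PSA run with n = ", n,
            " draws; at least 10,000 are recommended for stable results",
            call. = FALSE)
  }
  psa <- sample_psa(inp$params, inp$lt, n = n, seed = seed)
  cc <- ceac(psa, wtp_grid)

  draws_file <- file.path(out_dir, "psa_draws.csv")
  ceac_file <- file.path(out_dir, "ceac.csv")
  utils::write.csv(psa$draws, draws_file, row.names = FALSE)
  utils::write.csv(cc, ceac_file, row.names = FALSE)
  outputs <- c(draws_file, ceac_file)
  if (isTRUE(plot)) {
    sfile <- file.path(out_dir, "psa_scatter.pdf")
    cfile <- file.path(out_dir, "ceac.pdf")
    .save_plot(plot_psa_scatter(psa, st$wtp_threshold), sfile)
    .save_plot(plot_ceac(cc, st$wtp_threshold), cfile)
    outputs <- c(outputs, sfile, cfile)
  }
  .write_manifest("run_psa", config_path, seed, out_dir, outputs)

  at_wtp <- mean(net_monetary_benefit(psa$draws$delta_cost,
                                      psa$draws$delta_qaly,
                                      st$wtp_threshold) > 0)
  message(sprintf("PSA: %d draws (seed %d); %.1f%% accepted at WTP $%s/QALY",
                  n, seed, 100 * at_wtp,
                  format(st$wtp_threshold, big.mark = ",")))
  invisible(list(psa = psa, ceac = cc))
}
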