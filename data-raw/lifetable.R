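# Builds inst/extdata/lifetable_us_synthetic.tsv: a synthetic US-like
# all-population period life table (ages 0-100) from a Gompertz-Makeham
# hazard h(x) = makeham + a * exp(b * x).
#
# Shape: makeham = 5e-4 (young-adult background mortality) and b = 0.09 per
# year (typical adult log-mortality slope in recent US tables). The baseline
# a is calibrated so that the remaining undiscounted life expectancy of the
# base-case cohort discharged at age 58.767 (58.6 + 2 monthly acute cycles),
# evaluated by the package's own half-cycle-corrected monthly engine
# truncated at age 100, equals 22.189 years -- the value consistent with
# recent (2020-2021 era) US period mortality at that age.
#
# Run from the package root: Rscript data-raw/lifetable.R

devtools::load_all(".", quiet = TRUE)

makeham <- 5e-4
b <- 0.09
target_le <- 22.189
params <- default_parameters()
discharge_age <- params$settings$start_age + params$settings$acute_phase_cycles / 12

le_given_a <- function(a) {
  lt <- make_gompertz_table(a, b, start_age = 0, terminal_age = 100,
                            makeham = makeham)
  vilocea:::.cohort_totals(discharge_age, lt, params$utilities,
                           params$settings)$ly
}

a <- exp(uniroot(function(la) le_given_a(exp(la)) - target_le,
                 c(log(1e-6), log(1e-2)), tol = 1e-12)$root)
cat(sprintf("calibrated a = %.12e (LE check: %.6f)\n", a, le_given_a(a)))

lt <- make_gompertz_table(a, b, start_age = 0, terminal_age = 100,
                          makeham = makeham)
write_life_table(lt, "inst/extdata/lifetable_us_synthetic.tsv")
cat("wrote inst/extdata/lifetable_us_synthetic.tsv\n")
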