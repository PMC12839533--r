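# Base-case configuration: vilobelimab + SoC vs SoC alone (both with
# immunomodulators) in mechanically ventilated COVID-19 patients.
# Arms are listed reference first. Probabilities are fractions, money in
# USD, durations in days, ages in years.
#
# uncertainty: low/high ranges are read as 95% intervals (sd = range/3.92);
# entries with a printed sd use it directly; family "fixed" parameters
# (unit costs) are varied only in the one-way DSA, never sampled in the PSA.
# The intervention RRT-duration range is the symmetric 5.8-7.8 days: the
# published 7.8-8.8 range does not bracket its own 6.8-day base value and is
# treated as a typographical error (see the methods vignette).

arms:
  soc:
    survival_60d: 0.51
    p_rrt: 0.157
    rrt_days: 9.4
    n_drug_administrations: 0.0
  vilobelimab:
    survival_60d: 0.82
    p_rrt: 0.096
    rrt_days: 6.8
    n_drug_administrations: 4.8
costs:
  icu_cost: 100461.0
  rrt_cost_per_day: 2000.0
  drug_cost_per_admin: 6350.0
utilities:
  age_band_utilities:
  - min: 0.0
    max: 50.0
    utility: 0.87
  - min: 50.0
    max: 60.0
    utility: 0.84
  - min: 60.0
    max: 70.0
    utility: 0.82
  - min: 70.0
    max: 80.0
    utility: 0.79
  - min: 80.0
    max: 200.0
    utility: 0.74
  mv_disutility: 0.56
  postdischarge_disutility_by_year:
  - 0.13
  - 0.067
  - 0.062
  - 0.026
settings:
  start_age: 58.600000000000001
  acute_phase_cycles: 2.0
  annual_discount_rate: 0.03
  horizon_age: 100.0
  wtp_threshold: 50000.0
  evly_reference_utility: 0.851
  n_psa_draws: 10000.0
  rng_seed: 1234.0
uncertainty:
- path: arms.vilobelimab.survival_60d
  family: beta
  low: 0.65
  high: 0.93
- path: arms.soc.survival_60d
  family: beta
  low: 0.34
  high: 0.66
- path: settings.start_age
  family: normal
  low: 22.0
  high: 79.0
- path: arms.vilobelimab.p_rrt
  family: beta
  low: 0.086
  high: 0.106
- path: arms.soc.p_rrt
  family: beta
  low: 0.141
  high: 0.173
- path: arms.vilobelimab.rrt_days
  family: gamma
  low: 5.8
  high: 7.8
- path: arms.soc.rrt_days
  family: gamma
  low: 8.1
  high: 10.699999999999999
- path: costs.rrt_cost_per_day
  family: fixed
  low: 1800.0
  high: 2200.0
- path: costs.drug_cost_per_admin
  family: fixed
  low: 5715.0
  high: 6985.0
- path: costs.icu_cost
  family: fixed
  low: 40218.0
  high: 100461.0
- path: utilities.age_band_utilities.1.utility
  family: beta
  sd: 0.002
- path: utilities.age_band_utilities.2.utility
  family: beta
  sd: 0.003
- path: utilities.age_band_utilities.3.utility
  family: beta
  sd: 0.003
- path: utilities.age_band_utilities.4.utility
  family: beta
  sd: 0.004
- path: utilities.age_band_utilities.5.utility
  family: beta
  sd: 0.006
- path: utilities.mv_disutility
  family: beta
  sd: 0.3
- path: utilities.postdischarge_disutility_by_year.1
  family: beta
  sd: 0.013
- path: utilities.postdischarge_disutility_by_year.2
  family: beta
  sd: 0.007
- path: utilities.postdischarge_disutility_by_year.3
  family: beta
  sd: 0.006
- path: utilities.postdischarge_disutility_by_year.4
  family: beta
  sd: 0.001

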