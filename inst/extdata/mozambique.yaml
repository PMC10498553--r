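# Mozambique HIV treatment case study: base-case parameter set for the
# cost-effectiveness comparison of six ARV delivery strategies.
# Base values are PERT modes; `pert` blocks give the sensitivity range used
# by the probabilistic sensitivity analysis. Currency: 2020 USD.
# The >80 starting-age mass is folded into the 75-80 band (model entry ages
# are 15-80); the printed age column sums to 100.01% and is renormalized on
# load.
parameters:
  n_plhiv: {value: 1970000}
  age_distribution:
    value:
      a15_19: 0.0438
      a20_24: 0.0992
      a25_29: 0.1525
      a30_34: 0.1637
      a35_39: 0.1582
      a40_44: 0.1422
      a45_49: 0.1089
      a50_54: 0.0558
      a55_59: 0.0331
      a60_64: 0.0197
      a65_69: 0.0118
      a70_74: 0.0065
      a75_80: 0.0047
  cd4_distribution_at_init:
    value: {gt500: 0.31, c350_500: 0.19, c200_349: 0.23, lt200: 0.27}
  mortality_rate_by_cd4_untreated:   # per 100 person-years, untreated HIV
    value: {gt500: 0.6, c350_500: 1.6, c200_349: 4.2, lt200: 21.2}
    pert:
      gt500: {min: 0.1, max: 2.0}
      c350_500: {min: 0.8, max: 3.0}
      c200_349: {min: 2.8, max: 5.7}
      lt200: {min: 13.2, max: 41.5}
  cd4_decline_no_art:                # cells/uL per year
    value: 60
    pert: {min: 50, max: 80}
  cd4_decline_on_art_failing:        # cells/uL per year (failing second line)
    value: 14
    pert: {min: 0, max: 20}
  cd4_gain_on_art:                   # cells/uL per year
    value: 205
    pert: {min: 170, max: 250}
  ltfu_12m_risk_1month:              # 12-month LTFU risk, 1-month clinical
    value: 0.20
    pert: {min: 0.12, max: 0.32}
  ltfu_rate_community_3m:            # per 100 person-years
    value: 5.1
    pert: {min: 1.59, max: 8.61}
  or_ltfu_3m:                        # 2-year LTFU odds ratio vs 1-month
    value: 0.79
    pert: {min: 0.76, max: 0.82}
  or_ltfu_6m:
    value: 0.41
    pert: {min: 0.31, max: 0.54}
  reengage_12m_with_tracing:         # probability over 12 months after LTFU
    value: 0.371
    pert: {min: 0.30, max: 0.44}
  reengage_12m_without_tracing:
    value: 0.151
    pert: {min: 0.08, max: 0.22}
  pct_first_line:
    value: 0.95
    pert: {min: 0.75, max: 0.98}
  pct_dolutegravir:                  # first-line regimen share (rest EFV)
    value: 0.99
  second_line_failure_rate:          # per 100 person-years
    value: 15
    pert: {min: 13, max: 18}
  annual_switch_risk_dtg:            # annual first->second line risk
    value: 0.0025
    pert: {min: 0.0, max: 0.005}
  annual_switch_risk_efv:
    value: 0.025
    pert: {min: 0.020, max: 0.033}
  discount_rate: {value: 0.05}
  daly_weight_on_art:
    value: {gt500: 0.078, c350_500: 0.1, c200_349: 0.15, lt200: 0.2}
  daly_weight_off_art:
    value: {gt500: 0.012, c350_500: 0.27, c200_349: 0.377, lt200: 0.58}
  facility_cost_1m_annual:           # USD/person-year, excl. ARVs
    value: 134
    pert: {min: 104, max: 163}
  community_cost_3m_annual:          # USD/person-year, excl. ARVs
    value: 160
    pert: {min: 125, max: 226}
  arv_cost_monthly_dtg: {value: 5.55}
  arv_cost_monthly_efv: {value: 6.40}
  arv_cost_monthly_second_line: {value: 23.15}
  vl_test_cost_annual:               # USD/person-year
    value: 26
    pert: {min: 20, max: 43}
  case_mgmt_cost_monthly:            # USD/person-month
    value: 37.97
    pert: {min: 25, max: 50}
  chapa_cost_per_hour:               # minibus taxi fare, USD/hour
    value: 0.28
    pert: {min: 0.05, max: 1.00}
  transit_time_distribution:         # round trip by chapa
    value: {lt60min: 0.51, m60_240min: 0.43, gt240min: 0.06}
  walk_roundtrip_hours:
    value: 6
    pert: {min: 1, max: 24}
  pct_travel_by_chapa:
    value: 0.575
    pert: {min: 0.33, max: 0.66}
  brigade_distance_fraction:         # distance to brigade site vs clinic
    value: 0.33
    pert: {min: 0.15, max: 0.50}
  wait_time_hours:
    value: 1
    pert: {min: 0.25, max: 4}
  oop_health_expenditure_annual: {value: 4.14}
  net_national_income_pc: {value: 393}
  gdp_pc: {value: 467}
strategies:
  - {id: clinical_1m, refill_interval_months: 1, setting: clinic,
     tracing_enabled: false}
  - {id: clinical_3m, refill_interval_months: 3, setting: clinic,
     tracing_enabled: false}
  - {id: clinical_6m, refill_interval_months: 6, setting: clinic,
     tracing_enabled: false}
  - {id: clinical_3m_case_mgmt, refill_interval_months: 3, setting: clinic,
     tracing_enabled: true}
  - {id: community_3m, refill_interval_months: 3, setting: community,
     tracing_enabled: false}
  - {id: mixed_6m_community_3m, refill_interval_months: 6, setting: mixed,
     tracing_enabled: false, mixed_allocation: 0.5}
run:
  n_individuals: 200000
  horizon_years: 100
  cycle_months: 1
  seed: 42
  psa_draws: 1000
  psa_n_individuals: 2000
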