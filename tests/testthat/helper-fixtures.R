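# Shared fixtures; everything is generated in code.

.fixture_cache <- new.env(parent = emptyenv())

moz <- function() {
  if (is.null(.fixture_cache$moz)) .fixture_cache$moz <- mozambique_config()
  .fixture_cache$moz
}

# A parameter set with every hazard zeroed and costs/weights controllable:
# the degenerate world where the engine must match closed forms exactly.
degenerate_params <- function(base = moz()$params,
                              monthly_cost = 0, daly_w = 0,
                              mortality = 0) {
  vals <- base$values
  vals$mortality_rate_by_cd4_untreated[] <- mortality
  vals$ltfu_12m_risk_1month <- 0
  vals$ltfu_rate_community_3m <- 0
  vals$annual_switch_risk_dtg <- 0
  vals$annual_switch_risk_efv <- 0
  vals$second_line_failure_rate <- 0
  vals$cd4_gain_on_art <- 0
  vals$cd4_decline_no_art <- 0
  vals$cd4_decline_on_art_failing <- 0
  vals$pct_first_line <- 1
  vals$pct_dolutegravir <- 1
  vals$daly_weight_on_art[] <- daly_w
  vals$daly_weight_off_art[] <- daly_w
  # route a flat monthly cost through the ARV component only
  vals$arv_cost_monthly_dtg <- monthly_cost
  vals$arv_cost_monthly_efv <- monthly_cost
  vals$arv_cost_monthly_second_line <- monthly_cost
  vals$facility_cost_1m_annual <- 0
  vals$community_cost_3m_annual <- 0
  vals$vl_test_cost_annual <- 0
  vals$case_mgmt_cost_monthly <- 0
  vals$chapa_cost_per_hour <- 0
  vals$walk_roundtrip_hours <- 0
  vals$wait_time_hours <- 0
  vals$net_national_income_pc <- 0  # zero time value: free visits
  parameter_set(vals)
}

clinic_1m <- function() strategy_definition("clinical_1m", 1L, "clinic")

# Published reference (cost, effect) points per perspective.
reference_points <- function(perspective) {
  ref <- reference_results(perspective)
  data.frame(strategy = ref$strategy, cost = ref$total_cost,
             effect = ref$dalys_averted)
}

# Minimal synthetic ICER tables realizing each reachable combination of
# (same optimal, on patient frontier) at lambda = 100; the health-sector
# optimum is always "b".
frame_case <- function(same_optimal, on_frontier) {
  hs <- build_icer_table(data.frame(strategy = c("a", "b"),
                                    cost = c(0, 10), effect = c(0, 2)))
  pat <- if (same_optimal) {
    build_icer_table(data.frame(strategy = c("a", "b"),
                                cost = c(0, 1), effect = c(0, 2)))
  } else if (on_frontier) {
    build_icer_table(data.frame(strategy = c("a", "b", "c"),
                                cost = c(0, 1, 3), effect = c(0, 2, 3)))
  } else {
    build_icer_table(data.frame(strategy = c("a", "b", "c"),
                                cost = c(0, 1, 0.5), effect = c(0, 2, 3)))
  }
  list(hs = hs, pat = pat)
}

# The truth table of the five-pattern framework over the reachable cube.
frame_truth_table <- function() {
  rbind(
    data.frame(same = TRUE,  frontier = TRUE,  affordable = TRUE,
               pattern = "perfectly_congruent"),
    data.frame(same = FALSE, frontier = TRUE,  affordable = TRUE,
               pattern = "weakly_congruent"),
    data.frame(same = FALSE, frontier = FALSE, affordable = TRUE,
               pattern = "incongruent"),
    data.frame(same = TRUE,  frontier = TRUE,  affordable = FALSE,
               pattern = "consistent"),
    data.frame(same = FALSE, frontier = TRUE,  affordable = FALSE,
               pattern = "consistent"),
    data.frame(same = FALSE, frontier = FALSE, affordable = FALSE,
               pattern = "inconsistent"))
}

# Desk-scale base case of the Mozambique analysis: per-strategy means
# averaged over 5 seeds at n = 10,000 (cached across acceptance tests).
acceptance_base_case <- function() {
  if (!is.null(.fixture_cache$base10k)) return(.fixture_cache$base10k)
  cfg <- moz()
  per_seed <- lapply(101:105, function(seed) {
    rows <- lapply(cfg$strategies, function(s) {
      co <- simulate_cohort(cfg$params, s, cfg$run, seed = seed, n = 10000)
      m <- co$summary$mean
      data.frame(strategy = s$id, cost_patient = m[["cost_patient_disc"]],
                 cost_hs = m[["cost_hs_disc"]], dalys = m[["dalys_disc"]],
                 years_on_art = m[["years_on_art"]],
                 survival = m[["survival_years"]])
    })
    do.call(rbind, rows)
  })
  stacked <- do.call(rbind, per_seed)
  base <- aggregate(cbind(cost_patient, cost_hs, dalys, years_on_art,
                          survival) ~ strategy, stacked, mean)
  .fixture_cache$base10k <- base
  base
}
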