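# Per-cycle costs under the patient and health-sector perspectives.
#
# The health-sector side follows the published cost components directly
# (facility / community service cost, ARV regimen price, viral load testing,
# case management). The patient side is a reconstruction: out-of-pocket
# transport fares plus travel and waiting time valued at an hourly wage
# proxy. See the methods vignette for the reconstruction choices.

#' Hourly value of patient time
#'
#' Adjusted net national income per capita divided by 2,000 working hours a
#' year — the conventional human-capital proxy for valuing travel and wait
#' time.
#'
#' @param params A `perspecta_params`.
#' @return USD per hour.
#' @export
time_value_per_hour <- function(params) {
  pv(params, "net_national_income_pc") / 2000
}

#' Expected round-trip transit time by minibus taxi
#'
#' Expectation over the three reported transit-time bands using midpoints
#' 0.5 h (<60 min) and 2.5 h (60-240 min), and 5 h for >240 min.
#'
#' @param params A `perspecta_params`.
#' @return Hours.
#' @export
expected_transit_hours <- function(params) {
  sum(pv(params, "transit_time_distribution") * .transit_midpoints_h)
}

#' Expected patient cost of one visit
#'
#' Mixture over travel mode: with probability `pct_travel_by_chapa` the
#' visit costs `fare_per_hour x transit_hours` out of pocket plus time valued
#' at `w` per hour for `transit_hours + wait`; otherwise the patient walks,
#' costing `w x (walk_hours + wait)`. Community (mobile brigade) visits
#' scale travel time — and hence the fare — by `brigade_distance_fraction`;
#' waiting time is unchanged.
#'
#' @param params A `perspecta_params`.
#' @param setting `"clinic"` or `"community"`.
#' @return Expected USD per visit.
#' @export
expected_patient_cost_per_visit <- function(params,
                                            setting = c("clinic",
                                                        "community")) {
  setting <- match.arg(setting)
  w <- time_value_per_hour(params)
  wait <- pv(params, "wait_time_hours")
  frac <- if (setting == "community")
    pv(params, "brigade_distance_fraction") else 1
  h_chapa <- expected_transit_hours(params) * frac
  h_walk <- pv(params, "walk_roundtrip_hours") * frac
  p_chapa <- pv(params, "pct_travel_by_chapa")
  fare <- pv(params, "chapa_cost_per_hour")
  cost_chapa <- fare * h_chapa + w * (h_chapa + wait)
  cost_walk <- w * (h_walk + wait)
  p_chapa * cost_chapa + (1 - p_chapa) * cost_walk
}

#' Visit schedule for a strategy
#'
#' All strategies revert to monthly clinic visits during the first 3 months
#' on ART and while CD4 < 200 (proxy for WHO clinical stage III/IV);
#' otherwise refill visits occur every `refill_interval_months` (clinic) or
#' every 3 months (community), expressed here as expected visits per month.
#'
#' @param strategy An atomic `perspecta_strategy` (not mixed; see
#'   [component_arms()]).
#' @param months_on_art Cumulative months on ART.
#' @param band Current CD4 band.
#' @return List with `visits` (per month) and `setting` of those visits.
#' @export
visit_schedule <- function(strategy, months_on_art, band) {
  stopifnot(inherits(strategy, "perspecta_strategy"))
  if (strategy$setting == "mixed")
    stop("mixed strategy has no single schedule; use component_arms()")
  if (months_on_art < 3 || band == "lt200")
    return(list(visits = 1, setting = "clinic"))
  if (strategy$setting == "community")
    return(list(visits = 1 / 3, setting = "community"))
  list(visits = 1 / strategy$refill_interval_months, setting = "clinic")
}

#' Patient-perspective cost of one monthly cycle
#'
#' Visits this month times the expected per-visit cost for the applicable
#' setting; zero while off ART (no service contact).
#'
#' @param params A `perspecta_params`.
#' @param strategy An atomic `perspecta_strategy`.
#' @param months_on_art Cumulative months on ART.
#' @param band Current CD4 band.
#' @param on_art Whether the person is on ART this cycle.
#' @return USD per month.
#' @export
patient_cost_per_cycle <- function(params, strategy, months_on_art = 12,
                                   band = "gt500", on_art = TRUE) {
  if (!on_art) return(0)
  sched <- visit_schedule(strategy, months_on_art, band)
  sched$visits * expected_patient_cost_per_visit(params, sched$setting)
}

#' Health-sector cost of one monthly cycle
#'
#' ARV regimen price (first-line dolutegravir or efavirenz, or the
#' second-line ritonavir-based regimen) plus the service component — the
#' annual 1-month clinical facility cost divided by 12 and scaled by visit
#' frequency for longer clinic intervals, or the flat community distribution
#' cost — plus monthly viral-load testing, plus the case-management cost in
#' strategies that include LTFU case management. Zero while off ART.
#'
#' @param params A `perspecta_params`.
#' @param strategy An atomic `perspecta_strategy`.
#' @param on_art Whether the person is on ART this cycle.
#' @param line `"first"` or `"second"`.
#' @param regimen First-line base drug, `"dtg"` or `"efv"`.
#' @param months_on_art Cumulative months on ART.
#' @param band Current CD4 band.
#' @return USD per month.
#' @export
health_sector_cost_per_cycle <- function(params, strategy, on_art = TRUE,
                                         line = c("first", "second"),
                                         regimen = c("dtg", "efv"),
                                         months_on_art = 12,
                                         band = "gt500") {
  line <- match.arg(line)
  regimen <- match.arg(regimen)
  stopifnot(inherits(strategy, "perspecta_strategy"))
  if (strategy$setting == "mixed")
    stop("mixed strategy has no single cost; use component_arms()")
  if (!on_art) return(0)
  arv <- if (line == "second") {
    pv(params, "arv_cost_monthly_second_line")
  } else if (regimen == "dtg") {
    pv(params, "arv_cost_monthly_dtg")
  } else {
    pv(params, "arv_cost_monthly_efv")
  }
  sched <- visit_schedule(strategy, months_on_art, band)
  service <- if (sched$setting == "community") {
    pv(params, "community_cost_3m_annual") / 12
  } else {
    # per-visit share of the monthly-distribution facility cost
    (pv(params, "facility_cost_1m_annual") / 12) * sched$visits
  }
  cm <- if (strategy$tracing_enabled) pv(params, "case_mgmt_cost_monthly")
        else 0
  arv + service + pv(params, "vl_test_cost_annual") / 12 + cm
}

#' Audit table of per-cycle costs
#'
#' One row per (arm, phase, CD4 severity, treatment line) with the monthly
#' cost under each perspective; intended for CSV export and eyeballing.
#'
#' @param params A `perspecta_params`.
#' @param strategy A `perspecta_strategy` (mixed allowed; arms expand).
#' @return data.frame.
#' @export
cost_audit_table <- function(params, strategy) {
  rows <- list()
  for (arm in component_arms(strategy)) {
    s <- arm$strategy
    for (phase in c("initiation", "established")) {
      moa <- if (phase == "initiation") 0 else 12
      for (band in c("gt500", "lt200")) {
        for (line in c("first", "second")) {
          rows[[length(rows) + 1L]] <- data.frame(
            arm = s$id, phase = phase, band = band, line = line,
            patient_usd_month = patient_cost_per_cycle(params, s, moa, band),
            health_sector_usd_month = health_sector_cost_per_cycle(
              params, s, TRUE, line, "dtg", moa, band))
        }
      }
    }
  }
  do.call(rbind, rows)
}
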