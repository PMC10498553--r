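# State space and per-cycle transition probabilities.
#
# 17 health states: 4 CD4 bands x 4 care statuses (on first-line ART,
# off ART but first-line eligible, on second-line ART, off ART second-line
# only) plus an absorbing death state. Within a cycle, events resolve by
# sequential conditional draws in the fixed order
#   death -> LTFU / re-engagement -> line switch / second-line failure
#   -> CD4 band drift,
# so per-state outgoing probability mass (with stay as the residual) sums to
# one by construction.

#' Convert an event rate to a monthly probability
#'
#' Constant-hazard (exponential) conversion: `p = 1 - exp(-rate / 1200)` for
#' a rate expressed per 100 person-years.
#'
#' @param rate Events per 100 person-years; must be >= 0.
#' @return Monthly probability, strictly below 1, monotone in `rate`.
#' @examples
#' rate_to_monthly_prob(21.2)  # 0.017512
#' @export
rate_to_monthly_prob <- function(rate) {
  if (any(rate < 0)) stop("rate must be nonnegative")
  1 - exp(-rate / 1200)
}

#' Convert an m-month risk to a monthly probability
#'
#' Geometric de-compounding: `p = 1 - (1 - P)^(1/m)`. Compounding `p` back
#' over `m` months recovers `P` exactly.
#'
#' @param P Probability of the event over `m` months, in `[0, 1)`.
#' @param m Window length in months, >= 1.
#' @return Monthly probability.
#' @examples
#' risk_to_monthly_prob(0.20, 12)
#' @export
risk_to_monthly_prob <- function(P, m) {
  if (any(P < 0) || any(P >= 1))
    stop("P must lie in [0, 1); P = 1 implies an infinite hazard")
  if (any(m < 1)) stop("m must be >= 1")
  1 - (1 - P)^(1 / m)
}

#' Adjust a probability by an odds ratio
#'
#' `P' = OR * o / (1 + OR * o)` with odds `o = P / (1 - P)`. `OR = 1` is the
#' identity; the result is monotone in `OR`.
#'
#' @param P_base Baseline probability, strictly inside (0, 1).
#' @param OR Odds ratio, > 0.
#' @return Adjusted probability.
#' @examples
#' apply_odds_ratio(0.5, 2)  # 2/3
#' @export
apply_odds_ratio <- function(P_base, OR) {
  if (any(P_base <= 0) || any(P_base >= 1))
    stop("P_base must be strictly inside (0, 1)")
  if (any(OR <= 0)) stop("OR must be positive")
  o <- OR * P_base / (1 - P_base)
  o / (1 + o)
}

#' Monthly CD4 band-crossing probability for an annual drift
#'
#' Expected-crossing-time approximation: an annual drift of `D` cells/uL
#' crosses a band of width `W` with monthly probability `min(1, |D|/(12 W))`;
#' the direction follows the sign of the drift. Individual CD4 counts are
#' not tracked, only bands.
#'
#' @param annual_drift Signed CD4 change in cells/uL/year (positive = toward
#'   higher CD4).
#' @param band One of [cd4_bands()]; widths are 150 cells/uL except `lt200`
#'   (200 cells/uL).
#' @return List with `prob` (monthly crossing probability of the current
#'   band) and `direction` (`"up"`, `"down"` or `"none"`).
#' @examples
#' cd4_band_transition_probs(-60, "c350_500")  # 0.0333 downward
#' @export
cd4_band_transition_probs <- function(annual_drift, band) {
  if (!band %in% cd4_bands()) stop("unknown CD4 band: ", band)
  if (annual_drift == 0)
    return(list(prob = 0, direction = "none"))
  list(prob = min(1, abs(annual_drift) / (12 * .band_widths[[band]])),
       direction = if (annual_drift > 0) "up" else "down")
}

# Monthly LTFU probabilities for a strategy: `forced` applies on the
# 1-month clinical schedule (first 3 months on ART or CD4 < 200), `regular`
# on the strategy's own distribution modality.
.ltfu_monthly <- function(params, strategy) {
  p1m <- risk_to_monthly_prob(pv(params, "ltfu_12m_risk_1month"), 12)
  reg <- if (strategy$setting == "community") {
    rate_to_monthly_prob(pv(params, "ltfu_rate_community_3m"))
  } else if (strategy$refill_interval_months == 1L) {
    p1m
  } else {
    # odds ratios are reported against the 1-month clinical distribution
    # over 2 years: compound the 12-month risk to 24 months, adjust, convert
    or <- pv(params, switch(as.character(strategy$refill_interval_months),
                            "3" = "or_ltfu_3m", "6" = "or_ltfu_6m"))
    p24 <- 1 - (1 - pv(params, "ltfu_12m_risk_1month"))^2
    risk_to_monthly_prob(apply_odds_ratio(p24, or), 24)
  }
  list(forced = p1m, regular = reg)
}

#' Build the per-cycle transition model for a strategy
#'
#' Composes the rate / risk / odds-ratio conversions into the monthly
#' probabilities the simulation engine consumes: untreated mortality by CD4
#' band, strategy-specific LTFU hazards, tracing-dependent re-engagement,
#' regimen-specific first-to-second-line switch risks, second-line failure,
#' and CD4 band drift (gain on suppressive ART, slow decline on failing
#' second-line ART, fast decline off ART). A mixed strategy returns one
#' model per component arm.
#'
#' @param params A `perspecta_params`.
#' @param strategy A `perspecta_strategy`.
#' @return A `perspecta_tmodel` (or `perspecta_tmodel_mixed` holding
#'   `arms = list(list(model, share), ...)`).
#' @export
build_transition_model <- function(params, strategy) {
  stopifnot(inherits(params, "perspecta_params"),
            inherits(strategy, "perspecta_strategy"))
  if (strategy$setting == "mixed") {
    arms <- lapply(component_arms(strategy), function(a)
      list(model = build_transition_model(params, a$strategy),
           share = a$share))
    return(structure(list(strategy = strategy, arms = arms),
                     class = c("perspecta_tmodel_mixed",
                               "perspecta_tmodel_base")))
  }
  bands <- cd4_bands()
  drift_vec <- function(drift, no_exit) {
    p <- vapply(bands, function(b)
      if (b == no_exit) 0 else cd4_band_transition_probs(drift, b)$prob,
      numeric(1))
    setNames(p, bands)
  }
  reengage_12m <- if (strategy$tracing_enabled)
    pv(params, "reengage_12m_with_tracing")
  else pv(params, "reengage_12m_without_tracing")
  ltfu <- .ltfu_monthly(params, strategy)
  m <- structure(list(
    strategy = strategy,
    p_death = setNames(
      rate_to_monthly_prob(pv(params, "mortality_rate_by_cd4_untreated")),
      bands),
    p_ltfu_forced = ltfu$forced,
    p_ltfu_regular = ltfu$regular,
    p_reengage = risk_to_monthly_prob(reengage_12m, 12),
    p_switch = c(dtg = risk_to_monthly_prob(
                   pv(params, "annual_switch_risk_dtg"), 12),
                 efv = risk_to_monthly_prob(
                   pv(params, "annual_switch_risk_efv"), 12)),
    p_fail_second = rate_to_monthly_prob(
      pv(params, "second_line_failure_rate")),
    p_up_on_art = drift_vec(pv(params, "cd4_gain_on_art"), "gt500"),
    p_down_failing = drift_vec(-pv(params, "cd4_decline_on_art_failing"),
                               "lt200"),
    p_down_off = drift_vec(-pv(params, "cd4_decline_no_art"), "lt200")
  ), class = c("perspecta_tmodel", "perspecta_tmodel_base"))
  probs <- unlist(m[c("p_death", "p_ltfu_forced", "p_ltfu_regular",
                      "p_reengage", "p_switch", "p_fail_second",
                      "p_up_on_art", "p_down_failing", "p_down_off")])
  bad <- probs < 0 | probs > 1
  if (any(bad))
    stop("transition model construction failed; probability outside [0, 1]: ",
         paste(names(probs)[bad], collapse = ", "))
  m
}

#' Joint outcome distribution of one cycle from a given state
#'
#' Enumerates the leaves of the sequential draw tree the engine walks
#' (death, then LTFU or re-engagement, then line switch or second-line
#' failure, then CD4 drift) and returns the probability of every joint
#' outcome. The probabilities sum to one: staying put is the residual leaf.
#'
#' @param model An atomic `perspecta_tmodel`.
#' @param band Current CD4 band.
#' @param care Current care status, one of `"on_first_line"`,
#'   `"off_art_first_line_eligible"`, `"on_second_line"`,
#'   `"off_art_second_line_only"`.
#' @param months_on_art Cumulative months on ART (drives the 1-month forced
#'   schedule during the first 3 months).
#' @param failing Whether second-line virological failure has occurred.
#' @param regimen First-line regimen, `"dtg"` or `"efv"`.
#' @return Named numeric vector of joint outcome probabilities.
#' @export
transition_distribution <- function(model, band, care, months_on_art = 12,
                                    failing = FALSE, regimen = "dtg") {
  stopifnot(inherits(model, "perspecta_tmodel"))
  if (!band %in% cd4_bands()) stop("unknown CD4 band: ", band)
  if (!care %in% .care_states) stop("unknown care status: ", care)
  leaves <- c(death = unname(model$p_death[band]))
  surv <- 1 - leaves[["death"]]
  bi <- match(band, cd4_bands())
  drift <- function(on_art, fail) {
    if (on_art && !fail) {
      up <- if (bi > 1) model$p_up_on_art[[band]] else 0
      c(up = up, down = 0)
    } else if (on_art && fail) {
      down <- if (bi < 4) model$p_down_failing[[band]] else 0
      c(up = 0, down = down)
    } else {
      down <- if (bi < 4) model$p_down_off[[band]] else 0
      c(up = 0, down = down)
    }
  }
  emit <- function(label, p_branch, on_art, fail) {
    d <- drift(on_art, fail)
    out <- c(p_branch * d[["up"]], p_branch * d[["down"]],
             p_branch * (1 - d[["up"]] - d[["down"]]))
    setNames(out, paste0(label, c("_cd4_up", "_cd4_down", "_cd4_stay")))
  }
  on_art <- care %in% c("on_first_line", "on_second_line")
  forced <- months_on_art < 3 || band == "lt200"
  out <- c()
  if (on_art) {
    pl <- if (forced) model$p_ltfu_forced else model$p_ltfu_regular
    # LTFU this cycle: off ART for the drift draw, no line event possible
    out <- c(out, emit("ltfu", surv * pl, FALSE, failing))
    stay_engaged <- surv * (1 - pl)
    if (care == "on_first_line") {
      psw <- model$p_switch[[regimen]]
      out <- c(out, emit("switch_to_second_line", stay_engaged * psw,
                         TRUE, FALSE))
      out <- c(out, emit("remain_first_line", stay_engaged * (1 - psw),
                         TRUE, FALSE))
    } else if (!failing) {
      pf <- model$p_fail_second
      out <- c(out, emit("second_line_failure", stay_engaged * pf,
                         TRUE, TRUE))
      out <- c(out, emit("remain_second_line", stay_engaged * (1 - pf),
                         TRUE, FALSE))
    } else {
      out <- c(out, emit("remain_second_line_failing", stay_engaged,
                         TRUE, TRUE))
    }
  } else {
    pr <- model$p_reengage
    out <- c(out, emit("reengage", surv * pr, TRUE, failing))
    out <- c(out, emit("remain_off_art", surv * (1 - pr), FALSE, failing))
  }
  c(leaves, out)
}

#' Tabulate a transition model for inspection / CSV export
#'
#' One row per (state, joint outcome, probability), over both the forced
#' 1-month phase and the strategy's regular schedule.
#'
#' @param model A `perspecta_tmodel` (atomic arm).
#' @return data.frame with columns `band`, `care`, `phase`, `event`, `prob`.
#' @export
transition_table <- function(model) {
  stopifnot(inherits(model, "perspecta_tmodel"))
  rows <- list()
  for (band in cd4_bands()) {
    for (care in .care_states) {
      for (phase in c("initiation", "established")) {
        dist <- transition_distribution(
          model, band, care, months_on_art = if (phase == "initiation") 0 else 12)
        rows[[length(rows) + 1L]] <- data.frame(
          band = band, care = care, phase = phase,
          event = names(dist), prob = unname(dist))
      }
    }
  }
  do.call(rbind, rows)
}
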