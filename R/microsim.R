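# Seeded individual-level Monte Carlo over monthly cycles with half-cycle
# corrected discounting. The inner loop lives in src/microsim.cpp; this file
# prepares engine inputs from the disease and cost models and assembles
# per-person results.

#' Discount an amount to present value
#'
#' `amount * (1 + d)^(-time_years)`; `d = 0` is the identity. Half-cycle
#' correction in the engine is implemented by evaluating each cycle's accrual
#' at its midpoint, i.e. `time_years = (t - 0.5) / 12` for cycle `t`.
#'
#' @param amount Numeric amount(s).
#' @param time_years Time in years.
#' @param d Annual discount rate, >= 0.
#' @return Discounted amount.
#' @examples
#' discount(100, 1, 0.05)  # 95.238
#' @export
discount <- function(amount, time_years, d) {
  if (any(d < 0)) stop("discount rate must be nonnegative")
  amount * (1 + d)^(-time_years)
}

#' DALY increment for time spent in a state
#'
#' Disability weight for the CD4 band and treatment status times the time
#' lived, in years. Years of life lost (weight 1 per year not lived before
#' the horizon) are handled separately by the engine.
#'
#' @param band CD4 band.
#' @param on_art Whether on ART.
#' @param params A `perspecta_params`.
#' @param cycle_fraction Time lived, in years.
#' @return DALYs.
#' @examples
#' # accrue_daly("gt500", TRUE, params, 1)  -> 0.078 with the packaged set
#' @export
accrue_daly <- function(band, on_art, params, cycle_fraction) {
  if (!band %in% cd4_bands()) stop("unknown CD4 band: ", band)
  w <- if (on_art) pv(params, "daly_weight_on_art")[[band]]
       else pv(params, "daly_weight_off_art")[[band]]
  w * cycle_fraction
}

# Per-arm constant inputs for the C++ engine. Costs are keyed by
# (line, regimen) and by schedule phase: "forced" = 1-month clinical
# (first 3 months on ART or CD4 < 200), "regular" = the arm's own modality.
.engine_inputs <- function(params, arm) {
  model <- build_transition_model(params, arm)
  hs <- function(moa, band) {
    c(health_sector_cost_per_cycle(params, arm, TRUE, "first", "dtg", moa, band),
      health_sector_cost_per_cycle(params, arm, TRUE, "first", "efv", moa, band),
      health_sector_cost_per_cycle(params, arm, TRUE, "second", "dtg", moa, band),
      health_sector_cost_per_cycle(params, arm, TRUE, "second", "efv", moa, band))
  }
  list(model = model,
       hs_forced = hs(0, "gt500"),
       hs_regular = hs(12, "gt500"),
       pat_forced = patient_cost_per_cycle(params, arm, 0, "gt500"),
       pat_regular = patient_cost_per_cycle(params, arm, 12, "gt500"))
}

.person_columns <- c("cost_patient_disc", "cost_hs_disc", "dalys_disc",
                     "cost_patient_undisc", "cost_hs_undisc", "dalys_undisc",
                     "survival_years", "years_on_art", "final_band",
                     "final_care")

#' Simulate a cohort under one strategy
#'
#' Runs the monthly-cycle Monte Carlo for `run$n_individuals` persons:
#' initial CD4 band from the initiation distribution, treatment line
#' Bernoulli(`pct_first_line`), first-line regimen
#' Bernoulli(`pct_dolutegravir`), starting age from the adult age
#' distribution (recorded; no age-specific dynamics). Costs accrue under
#' both perspectives in the same run; health outcomes are therefore
#' identical across perspectives. Results are bit-reproducible given
#' `(seed, n, params, strategy)`.
#'
#' @param params A `perspecta_params`.
#' @param strategy A `perspecta_strategy` (mixed strategies split the cohort
#'   permanently at baseline between their arms).
#' @param run A `perspecta_run`.
#' @param seed Integer seed; defaults to `run$seed`.
#' @param n Cohort size override; defaults to `run$n_individuals`.
#' @return A `perspecta_cohort`: list with `strategy`, `n`, `seed`,
#'   `person` (one row per person) and `summary` (means and Monte Carlo
#'   standard errors).
#' @export
simulate_cohort <- function(params, strategy, run, seed = NULL, n = NULL) {
  stopifnot(inherits(params, "perspecta_params"),
            inherits(strategy, "perspecta_strategy"),
            inherits(run, "perspecta_run"))
  n <- as.integer(n %||% run$n_individuals)
  if (is.na(n) || n < 1) stop("cohort size must be >= 1")
  seed <- as.integer(seed %||% run$seed)
  T <- as.integer(round(run$horizon_years * 12))
  d <- pv(params, "discount_rate")
  v <- (1 + d)^(-(seq_len(T) - 0.5) / 12)
  tail_disc <- rev(cumsum(rev(v))) / 12
  tail_undisc <- (T - seq_len(T) + 1) / 12

  set.seed(seed)
  band0 <- sample.int(4L, n, replace = TRUE,
                      prob = pv(params, "cd4_distribution_at_init"))
  care0 <- ifelse(runif(n) < pv(params, "pct_first_line"), 1L, 3L)
  reg0 <- ifelse(runif(n) < pv(params, "pct_dolutegravir"), 1L, 2L)
  age_band <- sample.int(13L, n, replace = TRUE,
                         prob = pv(params, "age_distribution"))
  start_age <- .age_lower[age_band] +
    runif(n) * (.age_upper[age_band] - .age_lower[age_band])
  arms <- component_arms(strategy)
  arm_id <- if (length(arms) == 2L)
    ifelse(runif(n) < arms[[1]]$share, 1L, 2L) else rep(1L, n)

  res <- matrix(NA_real_, n, 10L)
  for (k in seq_along(arms)) {
    idx <- which(arm_id == k)
    if (!length(idx)) next
    ei <- .engine_inputs(params, arms[[k]]$strategy)
    m <- ei$model
    res[idx, ] <- cpp_simulate_persons(
      T, v, tail_disc, tail_undisc,
      unname(m$p_death), m$p_ltfu_forced, m$p_ltfu_regular, m$p_reengage,
      unname(m$p_switch), m$p_fail_second,
      unname(m$p_up_on_art), unname(m$p_down_failing), unname(m$p_down_off),
      unname(pv(params, "daly_weight_on_art")),
      unname(pv(params, "daly_weight_off_art")),
      ei$hs_forced, ei$hs_regular, ei$pat_forced, ei$pat_regular,
      band0[idx], care0[idx], reg0[idx])
  }
  person <- as.data.frame(res)
  names(person) <- .person_columns
  person$final_band <- cd4_bands()[person$final_band]
  person$start_age <- start_age
  person$arm <- vapply(arms, function(a) a$strategy$id, "")[arm_id]

  num <- c("cost_patient_disc", "cost_hs_disc", "dalys_disc",
           "cost_patient_undisc", "cost_hs_undisc", "dalys_undisc",
           "survival_years", "years_on_art")
  means <- vapply(person[num], mean, numeric(1))
  ses <- vapply(person[num], function(x) sd(x) / sqrt(length(x)), numeric(1))
  structure(list(strategy = strategy$id, n = n, seed = seed,
                 horizon_years = run$horizon_years,
                 person = person,
                 summary = list(mean = means, se = ses)),
            class = "perspecta_cohort")
}

#' Simulate a single person
#'
#' Convenience wrapper around [simulate_cohort()] with `n = 1`.
#'
#' @inheritParams simulate_cohort
#' @return One-row data.frame of person results.
#' @export
simulate_person <- function(params, strategy, run, seed = NULL) {
  simulate_cohort(params, strategy, run, seed = seed, n = 1L)$person
}

#' @export
print.perspecta_cohort <- function(x, ...) {
  cat(sprintf("<perspecta cohort: %s, n = %d, seed = %d>\n",
              x$strategy, x$n, x$seed))
  m <- x$summary$mean
  cat(sprintf("  mean discounted cost: patient $%.2f, health sector $%.2f\n",
              m[["cost_patient_disc"]], m[["cost_hs_disc"]]))
  cat(sprintf("  mean discounted DALYs %.3f, survival %.1f y, ART %.1f y\n",
              m[["dalys_disc"]], m[["survival_years"]],
              m[["years_on_art"]]))
  invisible(x)
}

#' Run the probabilistic sensitivity analysis
#'
#' Draws `draws` parameter sets and simulates every strategy on each one
#' with common random numbers (the same cohort seed within a draw), so
#' between-strategy increments are not drowned in first-order noise.
#'
#' @param params Base-case `perspecta_params`.
#' @param strategies List of `perspecta_strategy`.
#' @param run A `perspecta_run`.
#' @param seed Master seed; defaults to `run$seed`.
#' @param draws Number of parameter draws; defaults to `run$psa_draws`.
#' @param n Persons per draw; defaults to `run$psa_n_individuals`.
#' @return data.frame with one row per (draw, strategy): discounted mean
#'   costs per perspective, mean DALY burden, mean years on ART.
#' @export
run_psa <- function(params, strategies, run, seed = NULL, draws = NULL,
                    n = NULL) {
  seed <- as.integer(seed %||% run$seed)
  draws <- as.integer(draws %||% run$psa_draws)
  n <- as.integer(n %||% run$psa_n_individuals)
  if (draws < 1) stop("PSA needs at least one draw")
  out <- vector("list", draws * length(strategies))
  k <- 0L
  for (dr in seq_len(draws)) {
    ps <- sample_parameter_set(params, seed + dr)
    cohort_seed <- seed + 100000L + dr
    for (s in strategies) {
      co <- simulate_cohort(ps, s, run, seed = cohort_seed, n = n)
      m <- co$summary$mean
      k <- k + 1L
      out[[k]] <- data.frame(draw = dr, strategy = s$id,
                             cost_patient = m[["cost_patient_disc"]],
                             cost_hs = m[["cost_hs_disc"]],
                             dalys = m[["dalys_disc"]],
                             years_on_art = m[["years_on_art"]])
    }
  }
  do.call(rbind, out)
}
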