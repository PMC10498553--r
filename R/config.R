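#' Define an ARV delivery strategy
#'
#' A strategy is characterized by its refill interval, delivery setting and
#' whether it includes loss-to-follow-up (LTFU) case management with patient
#' tracing. Every strategy additionally follows the national standard of
#' 1-month clinical refills during the first 3 months on ART and while in
#' severe disease (CD4 < 200, the model's proxy for WHO clinical stage
#' III/IV).
#'
#' @param id Strategy identifier (free string; the six packaged strategies
#'   use `clinical_1m`, `clinical_3m`, `clinical_6m`,
#'   `clinical_3m_case_mgmt`, `community_3m`, `mixed_6m_community_3m`).
#' @param refill_interval_months Refill interval, one of 1, 3, 6. For a
#'   mixed strategy this is the clinic arm's interval; the community arm is
#'   always 3-monthly.
#' @param setting `"clinic"`, `"community"` or `"mixed"`.
#' @param tracing_enabled Whether the strategy includes LTFU case management
#'   (patient tracing switches the 12-month re-engagement probability to the
#'   with-tracing value and adds the monthly case-management cost).
#' @param mixed_allocation For mixed strategies, the proportion of persons
#'   permanently assigned at baseline to the clinic arm (the remainder go to
#'   the community arm).
#' @return Object of class `perspecta_strategy`.
#' @export
strategy_definition <- function(id, refill_interval_months,
                                setting = c("clinic", "community", "mixed"),
                                tracing_enabled = FALSE,
                                mixed_allocation = NA_real_) {
  setting <- match.arg(setting)
  if (!refill_interval_months %in% c(1L, 3L, 6L))
    stop("refill_interval_months must be 1, 3 or 6 (strategy ", id, ")")
  if (setting == "mixed") {
    if (is.na(mixed_allocation) || mixed_allocation <= 0 ||
        mixed_allocation >= 1)
      stop("mixed strategy ", id, " needs mixed_allocation in (0, 1)")
  } else {
    mixed_allocation <- NA_real_
  }
  structure(list(id = as.character(id),
                 refill_interval_months = as.integer(refill_interval_months),
                 setting = setting,
                 tracing_enabled = isTRUE(tracing_enabled),
                 mixed_allocation = mixed_allocation),
            class = "perspecta_strategy")
}

#' Component arms of a strategy
#'
#' A mixed strategy assigns persons permanently at baseline to one of two
#' atomic arms; all other strategies are their own single arm.
#'
#' @param strategy A `perspecta_strategy`.
#' @return List of `list(strategy = <atomic strategy>, share = <proportion>)`.
#' @export
component_arms <- function(strategy) {
  stopifnot(inherits(strategy, "perspecta_strategy"))
  if (strategy$setting != "mixed")
    return(list(list(strategy = strategy, share = 1)))
  list(
    list(strategy = strategy_definition(
           paste0(strategy$id, ".clinic"),
           strategy$refill_interval_months, "clinic",
           strategy$tracing_enabled),
         share = strategy$mixed_allocation),
    list(strategy = strategy_definition(
           paste0(strategy$id, ".community"), 3L, "community",
           strategy$tracing_enabled),
         share = 1 - strategy$mixed_allocation))
}

#' The six packaged ARV delivery strategies
#'
#' @return List of `perspecta_strategy`: pre-Covid 1-month clinical refills,
#'   3-month clinical (status quo), 6-month clinical, 3-month clinical with
#'   LTFU case management, 3-month community distribution by mobile brigade,
#'   and a 50/50 mix of 6-month clinical and 3-month community.
#' @export
default_strategies <- function() {
  list(
    strategy_definition("clinical_1m", 1L, "clinic"),
    strategy_definition("clinical_3m", 3L, "clinic"),
    strategy_definition("clinical_6m", 6L, "clinic"),
    strategy_definition("clinical_3m_case_mgmt", 3L, "clinic",
                        tracing_enabled = TRUE),
    strategy_definition("community_3m", 3L, "community"),
    strategy_definition("mixed_6m_community_3m", 6L, "mixed",
                        mixed_allocation = 0.5)
  )
}

#' Default willingness-to-pay grid (USD per DALY averted)
#'
#' Dense near zero (where patient-perspective frontier ICERs live), coarser
#' toward the health-sector range.
#'
#' @return Strictly increasing numeric vector.
#' @export
default_wtp_grid <- function() {
  sort(unique(c(seq(0, 20, by = 0.5), seq(22, 200, by = 2),
                seq(210, 500, by = 10), seq(550, 2500, by = 50),
                seq(3000, 20000, by = 500))))
}

#' Run settings for a simulation / analysis
#'
#' @param n_individuals Cohort size for base-case runs (the full-scale case
#'   study uses 200,000).
#' @param horizon_years Simulation horizon in years (default 100, a lifetime
#'   analysis).
#' @param cycle_months Cycle length; only monthly cycles are supported.
#' @param seed Master integer seed; all randomness flows from it.
#' @param psa_draws Number of probabilistic-sensitivity-analysis parameter
#'   sets (full scale: 1000).
#' @param psa_n_individuals Cohort size per PSA draw.
#' @param wtp_grid Willingness-to-pay grid for acceptability curves.
#' @param wtp_threshold Decision threshold in USD per DALY averted; `NULL`
#'   means 0.3 x GDP per capita from the parameter set.
#' @param affordability_threshold Annual affordability threshold in USD;
#'   `NULL` means the average annual out-of-pocket health expenditure from
#'   the parameter set.
#' @return Object of class `perspecta_run`.
#' @export
run_config <- function(n_individuals = 200000L, horizon_years = 100,
                       cycle_months = 1L, seed = 42L, psa_draws = 1000L,
                       psa_n_individuals = 2000L, wtp_grid = default_wtp_grid(),
                       wtp_threshold = NULL, affordability_threshold = NULL) {
  rc <- structure(list(n_individuals = as.integer(n_individuals),
                       horizon_years = horizon_years,
                       cycle_months = as.integer(cycle_months),
                       seed = as.integer(seed),
                       psa_draws = as.integer(psa_draws),
                       psa_n_individuals = as.integer(psa_n_individuals),
                       wtp_grid = wtp_grid,
                       wtp_threshold = wtp_threshold,
                       affordability_threshold = affordability_threshold),
                  class = "perspecta_run")
  problems <- .validate_run(rc)
  if (length(problems))
    stop("invalid run config:\n  - ", paste(problems, collapse = "\n  - "))
  rc
}

.validate_run <- function(rc) {
  problems <- character()
  if (is.na(rc$n_individuals) || rc$n_individuals < 1)
    problems <- c(problems, "n_individuals: must be >= 1")
  if (!is.numeric(rc$horizon_years) || rc$horizon_years <= 0)
    problems <- c(problems, "horizon_years: must be > 0")
  if (rc$cycle_months != 1L)
    problems <- c(problems, "cycle_months: only 1-month cycles are supported")
  if (rc$psa_draws < 1)
    problems <- c(problems, "psa_draws: must be >= 1")
  if (rc$psa_n_individuals < 1)
    problems <- c(problems, "psa_n_individuals: must be >= 1")
  if (length(rc$wtp_grid) < 1 || any(diff(rc$wtp_grid) <= 0) ||
      any(rc$wtp_grid < 0))
    problems <- c(problems, "wtp_grid: must be nonnegative, strictly increasing")
  for (nm in c("wtp_threshold", "affordability_threshold")) {
    v <- rc[[nm]]
    if (!is.null(v) && (!is.numeric(v) || v <= 0))
      problems <- c(problems, paste0(nm, ": must be positive"))
  }
  problems
}

#' Validate a full configuration
#'
#' @param cfg A `perspecta_config` (list with `params`, `strategies`, `run`).
#' @return Character vector of diagnostics naming the offending field; empty
#'   when valid.
#' @export
validate_config <- function(cfg) {
  problems <- character()
  if (!inherits(cfg$params, "perspecta_params")) {
    problems <- c(problems, "params: missing or not a parameter set")
  } else {
    problems <- c(problems, validate_parameter_set(cfg$params))
  }
  ids <- vapply(cfg$strategies, function(s) s$id %||% NA_character_, "")
  if (length(ids) == 0) problems <- c(problems, "strategies: none defined")
  if (anyDuplicated(ids)) problems <- c(problems, "strategies: duplicate ids")
  if (!inherits(cfg$run, "perspecta_run")) {
    problems <- c(problems, "run: missing or not a run config")
  } else {
    problems <- c(problems, .validate_run(cfg$run))
  }
  problems
}

# Reorder a named value read from YAML into canonical element order.
.canonical_value <- function(nm, raw, sc) {
  v <- unlist(raw)
  if (!is.null(sc$names)) {
    if (is.null(names(v)) || !setequal(names(v), sc$names))
      stop("parameter ", nm, ": elements must be named (",
           paste(sc$names, collapse = ", "), ")")
    v <- v[sc$names]
  }
  as.numeric(v) -> out
  names(out) <- names(v)
  out
}

#' Read a model configuration from YAML
#'
#' The file has three sections: `parameters` (each entry a `value`, scalar or
#' named map, plus an optional `pert: {min, max}` block — per element for
#' vector parameters — with the base value as the mode), `strategies`, and
#' `run`. Categorical vectors whose printed values sum to within 0.5% of 1
#' (rounding in published tables) are renormalized; larger deviations are
#' validation errors.
#'
#' @param path Path to a YAML configuration.
#' @return A `perspecta_config`: list with `params` ([parameter_set()]),
#'   `strategies` (list of [strategy_definition()]) and `run`
#'   ([run_config()]).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  schema <- .param_schema()
  values <- list()
  dists <- list()
  for (nm in names(schema)) {
    node <- y$parameters[[nm]]
    if (is.null(node)) stop("config is missing parameter: ", nm)
    sc <- schema[[nm]]
    v <- .canonical_value(nm, node$value, sc)
    if (sc$simplex) {
      s <- sum(v)
      if (abs(s - 1) > 5e-3)
        stop("parameter ", nm, ": probabilities sum to ", format(s),
             ", not 1")
      v <- v / s
    }
    values[[nm]] <- v
    if (!is.null(node$pert)) {
      pert <- node$pert
      named_stop <- function(e) stop("parameter ", nm, ": ",
                                     conditionMessage(e), call. = FALSE)
      if (!is.null(pert$min)) {
        # scalar parameter: single {min, max} block, mode = base value
        dists[[nm]] <- list(tryCatch(dist_pert(pert$min, v[[1]], pert$max),
                                     error = named_stop))
      } else {
        specs <- list()
        for (el in names(pert)) {
          idx <- match(el, names(v))
          if (is.na(idx)) stop("parameter ", nm, ": pert element '", el,
                               "' does not match a value element")
          specs[[el]] <- tryCatch(
            dist_pert(pert[[el]]$min, v[[idx]], pert[[el]]$max),
            error = named_stop)
        }
        dists[[nm]] <- specs
      }
    }
  }
  params <- tryCatch(parameter_set(values, dists), error = function(e)
    stop("invalid config '", path, "': ", conditionMessage(e),
         call. = FALSE))
  strategies <- lapply(y$strategies, function(s) {
    strategy_definition(s$id, s$refill_interval_months, s$setting,
                        s$tracing_enabled %||% FALSE,
                        s$mixed_allocation %||% NA_real_)
  })
  run <- do.call(run_config, y$run %||% list())
  cfg <- structure(list(params = params, strategies = strategies, run = run),
                   class = "perspecta_config")
  problems <- validate_config(cfg)
  if (length(problems))
    stop("invalid config '", path, "':\n  - ",
         paste(problems, collapse = "\n  - "))
  cfg
}

#' Write a configuration back to YAML
#'
#' Round-trips with [load_config()]: loading the written file yields the same
#' values (to floating-point print precision of 15 significant digits).
#'
#' @param cfg A `perspecta_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  as_node <- function(nm) {
    v <- cfg$params$values[[nm]]
    node <- list(value = if (length(v) > 1) as.list(v) else unname(v))
    specs <- cfg$params$dists[[nm]]
    if (!is.null(specs)) {
      if (length(v) > 1 || !is.null(names(specs))) {
        node$pert <- lapply(specs, function(s) list(min = s$min, max = s$max))
      } else {
        node$pert <- list(min = specs[[1]]$min, max = specs[[1]]$max)
      }
    }
    node
  }
  params <- setNames(lapply(names(cfg$params$values), as_node),
                     names(cfg$params$values))
  strategies <- lapply(cfg$strategies, function(s) {
    out <- list(id = s$id, refill_interval_months = s$refill_interval_months,
                setting = s$setting, tracing_enabled = s$tracing_enabled)
    if (!is.na(s$mixed_allocation)) out$mixed_allocation <- s$mixed_allocation
    out
  })
  run <- cfg$run[!vapply(cfg$run, is.null, TRUE)]
  run$wtp_grid <- NULL  # regenerate defaults on load unless customized
  if (!identical(cfg$run$wtp_grid, default_wtp_grid()))
    run$wtp_grid <- cfg$run$wtp_grid
  yaml::write_yaml(list(parameters = params, strategies = strategies,
                        run = run),
                   path, precision = 15L)
  invisible(path)
}

#' Load the packaged Mozambique HIV treatment configuration
#'
#' Base-case values, PERT sensitivity ranges, the six delivery strategies and
#' the full-scale run settings of the Mozambique case study.
#'
#' @return A `perspecta_config`.
#' @export
mozambique_config <- function() {
  load_config(system.file("extdata", "mozambique.yaml",
                          package = "perspecta"))
}

#' Generate a randomized synthetic configuration for property tests
#'
#' Draws a valid, internally consistent parameter set within admissible
#' bounds, with a reduced cohort: `tiny` runs 500 individuals over a 10-year
#' horizon, `small` 2,000 over 20 years. The fixture is a pure function of
#' `seed`.
#'
#' @param seed Integer seed.
#' @param size `"tiny"` or `"small"`.
#' @return A `perspecta_config`.
#' @export
make_fixture <- function(seed, size = c("tiny", "small")) {
  size <- match.arg(size)
  set.seed(seed)
  r6 <- function(x) signif(x, 6)
  simplex <- function(n, names) {
    x <- runif(n) + 0.05
    x <- round(x / sum(x), 6)
    x[n] <- 1 - sum(x[-n])
    setNames(x, names)
  }
  pert_about <- function(mode, lo_f = 0.6, hi_f = 1.6, upper = Inf) {
    lo <- r6(max(0, mode * lo_f))
    hi <- r6(min(upper, mode * hi_f + 1e-4))
    dist_pert(lo, mode, hi)
  }
  vals <- list()
  dists <- list()
  add <- function(nm, mode, pert = TRUE, upper = Inf) {
    mode <- r6(mode)
    vals[[nm]] <<- mode
    if (pert) dists[[nm]] <<- list(pert_about(mode, upper = upper))
  }
  mort <- r6(c(runif(1, 0.2, 1), runif(1, 1, 3), runif(1, 3, 6),
               runif(1, 10, 40)))
  vals$mortality_rate_by_cd4_untreated <- setNames(mort, cd4_bands())
  dists$mortality_rate_by_cd4_untreated <-
    setNames(lapply(mort, pert_about), cd4_bands())
  add("cd4_decline_no_art", runif(1, 40, 90))
  add("cd4_decline_on_art_failing", runif(1, 5, 18))
  add("cd4_gain_on_art", runif(1, 150, 260))
  add("ltfu_12m_risk_1month", runif(1, 0.10, 0.35), upper = 1)
  add("ltfu_rate_community_3m", runif(1, 1, 9))
  or3 <- r6(runif(1, 0.6, 0.9))
  or6 <- r6(runif(1, 0.25, or3 - 0.05))
  vals$or_ltfu_3m <- or3; dists$or_ltfu_3m <- list(pert_about(or3))
  vals$or_ltfu_6m <- or6; dists$or_ltfu_6m <- list(pert_about(or6))
  add("reengage_12m_with_tracing", runif(1, 0.30, 0.45), upper = 1)
  add("reengage_12m_without_tracing", runif(1, 0.08, 0.22), upper = 1)
  add("pct_first_line", runif(1, 0.75, 0.98), upper = 1)
  add("pct_dolutegravir", runif(1, 0.90, 0.999), pert = FALSE)
  add("second_line_failure_rate", runif(1, 10, 20))
  add("annual_switch_risk_dtg", runif(1, 0.001, 0.005), upper = 1)
  add("annual_switch_risk_efv", runif(1, 0.02, 0.033), upper = 1)
  add("discount_rate", runif(1, 0.03, 0.07), pert = FALSE)
  w_on <- r6(sort(runif(4, 0.05, 0.3)))
  w_off <- r6(pmin(1, w_on + sort(runif(4, 0, 0.4))))
  vals$daly_weight_on_art <- setNames(w_on, cd4_bands())
  vals$daly_weight_off_art <- setNames(w_off, cd4_bands())
  add("facility_cost_1m_annual", runif(1, 80, 200))
  add("community_cost_3m_annual", runif(1, 100, 260))
  add("arv_cost_monthly_dtg", runif(1, 3, 9), pert = FALSE)
  add("arv_cost_monthly_efv", runif(1, 4, 10), pert = FALSE)
  add("arv_cost_monthly_second_line", runif(1, 15, 30), pert = FALSE)
  add("vl_test_cost_annual", runif(1, 15, 50))
  add("case_mgmt_cost_monthly", runif(1, 20, 60))
  add("chapa_cost_per_hour", runif(1, 0.05, 1))
  vals$transit_time_distribution <- simplex(3, .transit_bands)
  add("walk_roundtrip_hours", runif(1, 1, 12))
  add("pct_travel_by_chapa", runif(1, 0.3, 0.7), upper = 1)
  add("brigade_distance_fraction", runif(1, 0.15, 0.5), upper = 1)
  add("wait_time_hours", runif(1, 0.25, 4))
  add("oop_health_expenditure_annual", runif(1, 2, 20), pert = FALSE)
  add("net_national_income_pc", runif(1, 300, 900), pert = FALSE)
  add("gdp_pc", runif(1, 350, 1000), pert = FALSE)
  vals$age_distribution <- simplex(13, .age_bands)
  vals$cd4_distribution_at_init <- simplex(4, cd4_bands())
  vals$n_plhiv <- round(runif(1, 1e5, 3e6))
  params <- parameter_set(vals, dists)
  run <- if (size == "tiny") {
    run_config(n_individuals = 500L, horizon_years = 10, seed = seed,
               psa_draws = 20L, psa_n_individuals = 200L)
  } else {
    run_config(n_individuals = 2000L, horizon_years = 20, seed = seed,
               psa_draws = 50L, psa_n_individuals = 500L)
  }
  structure(list(params = params, strategies = default_strategies(),
                 run = run),
            class = "perspecta_config")
}
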