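# Parameter data model: one authoritative home per model symbol.
#
# Each entry fixes the expected length, canonical element names, bounds and
# whether the vector must be a probability simplex. Bounds also constrain
# PERT supports so that PSA draws can never violate an invariant.
.param_schema <- function() {
  num <- function(len = 1L, names = NULL, lower = 0, upper = Inf,
                  simplex = FALSE)
    list(len = len, names = names, lower = lower, upper = upper,
         simplex = simplex)
  bands <- cd4_bands()
  list(
    n_plhiv                         = num(lower = 1),
    age_distribution                = num(13L, .age_bands, 0, 1, TRUE),
    cd4_distribution_at_init        = num(4L, bands, 0, 1, TRUE),
    mortality_rate_by_cd4_untreated = num(4L, bands),
    cd4_decline_no_art              = num(),
    cd4_decline_on_art_failing      = num(),
    cd4_gain_on_art                 = num(),
    ltfu_12m_risk_1month            = num(upper = 1),
    ltfu_rate_community_3m          = num(),
    or_ltfu_3m                      = num(),
    or_ltfu_6m                      = num(),
    reengage_12m_with_tracing       = num(upper = 1),
    reengage_12m_without_tracing    = num(upper = 1),
    pct_first_line                  = num(upper = 1),
    pct_dolutegravir                = num(upper = 1),
    second_line_failure_rate        = num(),
    annual_switch_risk_dtg          = num(upper = 1),
    annual_switch_risk_efv          = num(upper = 1),
    discount_rate                   = num(upper = 1),
    daly_weight_on_art              = num(4L, bands, 0, 1),
    daly_weight_off_art             = num(4L, bands, 0, 1),
    facility_cost_1m_annual         = num(),
    community_cost_3m_annual        = num(),
    arv_cost_monthly_dtg            = num(),
    arv_cost_monthly_efv            = num(),
    arv_cost_monthly_second_line    = num(),
    vl_test_cost_annual             = num(),
    case_mgmt_cost_monthly          = num(),
    chapa_cost_per_hour             = num(),
    transit_time_distribution       = num(3L, .transit_bands, 0, 1, TRUE),
    walk_roundtrip_hours            = num(),
    pct_travel_by_chapa             = num(upper = 1),
    brigade_distance_fraction       = num(upper = 1),
    wait_time_hours                 = num(),
    oop_health_expenditure_annual   = num(),
    net_national_income_pc          = num(),
    gdp_pc                          = num()
  )
}

#' Construct a parameter set
#'
#' A parameter set couples base-case values (PERT modes for uncertain
#' parameters) with optional PERT distribution specifications used by the
#' probabilistic sensitivity analysis.
#'
#' @param values Named list of numeric values; vector-valued parameters must
#'   carry the canonical element names (see [cd4_bands()]).
#' @param dists Named list; each entry is a list of [dist_pert()]
#'   specifications parallel to the elements of the corresponding value.
#' @param sampled Set `TRUE` for a PSA draw: values must then lie within
#'   their PERT support rather than equal the mode.
#' @return Object of class `perspecta_params`.
#' @seealso [validate_parameter_set()], [sample_parameter_set()]
#' @export
parameter_set <- function(values, dists = list(), sampled = FALSE) {
  # canonical field order, so equality and round-trips are order-free
  canon <- names(.param_schema())
  if (all(canon %in% names(values)))
    values <- values[c(canon, setdiff(names(values), canon))]
  dists <- dists[intersect(canon, names(dists))]
  ps <- structure(list(values = values, dists = dists, sampled = sampled),
                  class = "perspecta_params")
  problems <- validate_parameter_set(ps)
  if (length(problems))
    stop("invalid parameter set:\n  - ", paste(problems, collapse = "\n  - "))
  ps
}

#' Validate a parameter set
#'
#' Checks every invariant of the parameter data model: field presence,
#' lengths, element names, bounds (probabilities in \[0, 1\], rates / costs /
#' times nonnegative), categorical vectors summing to 1 within 1e-9, and PERT
#' supports lying inside the parameter's admissible range with the base value
#' equal to the mode.
#'
#' @param ps A `perspecta_params` (or a bare list shaped like one).
#' @return Character vector of problems; empty when valid.
#' @export
validate_parameter_set <- function(ps) {
  schema <- .param_schema()
  problems <- character()
  vals <- ps$values
  for (nm in names(schema)) {
    sc <- schema[[nm]]
    v <- vals[[nm]]
    if (is.null(v)) {
      problems <- c(problems, paste0(nm, ": missing"))
      next
    }
    v <- unlist(v, use.names = TRUE)
    if (!is.numeric(v) || length(v) != sc$len) {
      problems <- c(problems, paste0(nm, ": expected numeric of length ",
                                     sc$len))
      next
    }
    if (!is.null(sc$names) && !identical(names(v), sc$names)) {
      problems <- c(problems, paste0(nm, ": element names must be (",
                                     paste(sc$names, collapse = ", "), ")"))
      next
    }
    if (any(!is.finite(v))) {
      problems <- c(problems, paste0(nm, ": non-finite value"))
      next
    }
    if (any(v < sc$lower) || any(v > sc$upper))
      problems <- c(problems, paste0(
        nm, ": value outside [", sc$lower, ", ", sc$upper, "]"))
    if (sc$simplex && abs(sum(v) - 1) > 1e-9)
      problems <- c(problems, paste0(nm, ": probabilities sum to ",
                                     format(sum(v)), ", not 1"))
  }
  extra <- setdiff(names(vals), names(schema))
  if (length(extra))
    problems <- c(problems, paste0("unknown parameter(s): ",
                                   paste(extra, collapse = ", ")))
  for (nm in names(ps$dists)) {
    if (!nm %in% names(schema)) {
      problems <- c(problems, paste0(nm, ": distribution for unknown parameter"))
      next
    }
    sc <- schema[[nm]]
    specs <- ps$dists[[nm]]
    v <- unlist(vals[[nm]])
    if (length(specs) > length(v)) {
      problems <- c(problems, paste0(nm, ": more distributions than elements"))
      next
    }
    for (i in seq_along(specs)) {
      spec <- specs[[i]]
      el <- names(specs)[i] %||% ""
      idx <- if (nzchar(el)) match(el, names(v)) else i
      lab <- if (nzchar(el)) paste0(nm, "[", el, "]") else nm
      if (!inherits(spec, "perspecta_dist") || spec$kind != "pert") {
        problems <- c(problems, paste0(lab, ": malformed distribution"))
        next
      }
      if (spec$min < sc$lower || spec$max > sc$upper)
        problems <- c(problems, paste0(
          lab, ": PERT support outside [", sc$lower, ", ", sc$upper, "]"))
      if (is.na(idx)) {
        problems <- c(problems, paste0(lab, ": no matching value element"))
      } else if (isTRUE(ps$sampled)) {
        if (v[idx] < spec$min - 1e-12 || v[idx] > spec$max + 1e-12)
          problems <- c(problems, paste0(
            lab, ": sampled value outside the PERT support"))
      } else if (abs(spec$mode - v[idx]) > 1e-9) {
        problems <- c(problems, paste0(
          lab, ": base value must equal the PERT mode"))
      }
    }
  }
  problems
}

# Scalar/vector accessor for a parameter value.
pv <- function(params, name) {
  v <- params$values[[name]]
  if (is.null(v)) stop("unknown parameter: ", name)
  unlist(v, use.names = TRUE)
}

#' Flatten a parameter set into a named numeric row
#'
#' Used for the one-row-per-draw CSV export of sampled PSA parameter sets.
#'
#' @param ps A `perspecta_params`.
#' @return Named numeric vector (vector elements expand to
#'   `name.element` columns).
#' @export
flatten_params <- function(ps) {
  unlist(ps$values, use.names = TRUE)
}

#' Draw one probabilistic-sensitivity-analysis parameter set
#'
#' Point parameters are carried through unchanged; each PERT parameter is
#' drawn independently from its scaled beta distribution. The draw is a pure
#' function of `(base, rng_seed)`, and the result always satisfies every
#' parameter-set invariant because PERT supports are validated against the
#' admissible range at load time.
#'
#' @param base Base-case `perspecta_params`.
#' @param rng_seed Integer seed.
#' @return A new `perspecta_params` with sampled values.
#' @export
sample_parameter_set <- function(base, rng_seed) {
  stopifnot(inherits(base, "perspecta_params"))
  set.seed(rng_seed)
  vals <- base$values
  for (nm in names(base$dists)) {
    specs <- base$dists[[nm]]
    v <- unlist(vals[[nm]], use.names = TRUE)
    for (i in seq_along(specs)) {
      el <- names(specs)[i]
      idx <- if (!is.null(el) && nzchar(el)) match(el, names(v)) else i
      v[idx] <- sample_dist(specs[[i]], 1)
    }
    vals[[nm]] <- v
  }
  parameter_set(vals, base$dists, sampled = TRUE)
}

#' @export
print.perspecta_params <- function(x, ...) {
  cat("<perspecta parameter set: ", length(x$values), " parameters, ",
      length(x$dists), " with PSA distributions>\n", sep = "")
  invisible(x)
}
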