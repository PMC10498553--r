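# Five-pattern congruence framework for comparing the health-sector and
# patient perspectives of a CEA on efficiency and affordability.

.pattern_next_steps <- c(
  perfectly_congruent = paste(
    "Both perspectives identify the same optimal strategy and it is",
    "affordable for patients: recommend it."),
  weakly_congruent = paste(
    "The health-sector optimum is efficient (on the patient-perspective",
    "frontier) and affordable, though not the patient-perspective optimum:",
    "recommend it, and consider design or incentive changes that steer",
    "patient choice toward it."),
  incongruent = paste(
    "The health-sector optimum is affordable but inefficient from the",
    "patient perspective: recommend it with caution, and redesign the",
    "intervention to improve its patient-perspective value, since patients",
    "face better-value alternatives."),
  consistent = paste(
    "The health-sector optimum is efficient from the patient perspective",
    "(possibly even their shared optimum) but unaffordable: redesign it to",
    "reduce or offset patients' out-of-pocket and time costs. If no",
    "affordable redesign exists, set it aside (without recalculating ICERs)",
    "and promote the next most cost-effective health-sector strategy that",
    "is efficient and affordable for patients."),
  inconsistent = paste(
    "The health-sector optimum is neither efficient nor affordable from",
    "the patient perspective: redesign it or set it aside (without",
    "recalculating ICERs) in favour of the next most cost-effective",
    "health-sector strategy that is efficient and affordable for patients.")
)

#' Classify the congruence of two CEA perspectives
#'
#' Determines the optimal strategy under each perspective at the
#' willingness-to-pay threshold, checks whether the health-sector optimum is
#' on the patient-perspective efficiency frontier (non-dominated, strictly or
#' extendedly), and combines this with its patient affordability into one of
#' five patterns:
#'
#' * affordable and same optimum -> `perfectly_congruent`
#' * affordable, on the patient frontier but not optimal -> `weakly_congruent`
#' * affordable, off the patient frontier -> `incongruent`
#' * unaffordable but on the patient frontier (or shared optimum) ->
#'   `consistent`
#' * unaffordable and off the patient frontier -> `inconsistent`
#'
#' @param hs_table Health-sector `perspecta_icer`.
#' @param patient_table Patient-perspective `perspecta_icer`.
#' @param lambda Willingness-to-pay threshold, > 0 (applied to both
#'   perspectives; pass `patient_lambda` if the payer thresholds differ).
#' @param affordability List `(affordable, ratio)` from
#'   [affordability_check()] for the health-sector optimum's equivalent
#'   annual patient cost.
#' @param patient_lambda Optional distinct threshold for the patient-side
#'   optimum.
#' @return A `perspecta_verdict`: pattern, the two optima, frontier and
#'   affordability evidence, and the recommended next step.
#' @export
classify_alignment <- function(hs_table, patient_table, lambda,
                               affordability, patient_lambda = lambda) {
  stopifnot(inherits(hs_table, "perspecta_icer"),
            inherits(patient_table, "perspecta_icer"))
  if (!is.finite(lambda) || lambda <= 0)
    stop("lambda must be positive")
  if (!all(c("affordable", "ratio") %in% names(affordability)))
    stop("affordability must be the (affordable, ratio) pair for the ",
         "health-sector optimum under the patient perspective")
  hs_opt <- optimal_at_wtp(hs_table, lambda)
  pat_opt <- optimal_at_wtp(patient_table, patient_lambda)
  if (!hs_opt %in% patient_table$strategy)
    stop("health-sector optimum '", hs_opt,
         "' is absent from the patient table")
  same <- hs_opt == pat_opt
  on_frontier <- same || hs_opt %in% frontier_strategies(patient_table)
  affordable <- isTRUE(affordability$affordable)
  pattern <- if (affordable) {
    if (same) "perfectly_congruent"
    else if (on_frontier) "weakly_congruent"
    else "incongruent"
  } else {
    if (on_frontier) "consistent" else "inconsistent"
  }
  structure(list(pattern = pattern,
                 hs_optimal = hs_opt,
                 patient_optimal = pat_opt,
                 hs_optimal_on_patient_frontier = on_frontier,
                 hs_optimal_affordable = affordable,
                 affordability_ratio = affordability$ratio,
                 lambda = lambda,
                 recommendation = unname(.pattern_next_steps[pattern])),
            class = "perspecta_verdict")
}

#' @export
print.perspecta_verdict <- function(x, ...) {
  cat("Perspective congruence verdict:", x$pattern, "\n")
  cat(sprintf("  health-sector optimum: %s | patient optimum: %s\n",
              x$hs_optimal, x$patient_optimal))
  cat(sprintf("  on patient frontier: %s | affordable: %s (ratio %.2f)\n",
              x$hs_optimal_on_patient_frontier, x$hs_optimal_affordable,
              x$affordability_ratio))
  cat("  next steps:", x$recommendation, "\n")
  invisible(x)
}

.format_icer_lines <- function(table, label) {
  c(sprintf("%s perspective:", label),
    sprintf("  %-24s cost %12.2f  effect %8.3f  %-21s ICER %s",
            table$strategy, table$cost, table$effect, table$status,
            ifelse(is.na(table$icer),
                   ifelse(table$status == "reference", "reference", "-"),
                   sprintf("%.2f", table$icer))))
}

#' Render a plain-text decision report
#'
#' Deterministic report containing both ICER ladders, every strategy's
#' equivalent annual patient cost against the affordability threshold, the
#' congruence verdict and its recommended next steps.
#'
#' @param verdict A `perspecta_verdict`.
#' @param hs_table,patient_table The two `perspecta_icer` tables.
#' @param affordability_table data.frame with columns `strategy`,
#'   `annual_cost`, `ratio`, `affordable` for all strategies (patient
#'   perspective).
#' @return Character vector of report lines.
#' @export
render_report <- function(verdict, hs_table, patient_table,
                          affordability_table) {
  stopifnot(inherits(verdict, "perspecta_verdict"))
  aff <- affordability_table
  lines <- c(
    "== Multi-perspective cost-effectiveness report ==",
    "",
    .format_icer_lines(hs_table, "Health sector"),
    "",
    .format_icer_lines(patient_table, "Patient"),
    "",
    "Affordability (equivalent annual patient cost vs threshold):",
    sprintf("  %-24s $%8.2f/yr  ratio %6.1f%%  %s",
            aff$strategy, aff$annual_cost, 100 * aff$ratio,
            ifelse(aff$affordable, "affordable", "unaffordable")),
    "",
    sprintf("Verdict: %s (threshold $%.2f per DALY averted)",
            verdict$pattern, verdict$lambda),
    sprintf("  Health-sector optimum: %s", verdict$hs_optimal),
    sprintf("  Patient optimum:       %s", verdict$patient_optimal))
  if (verdict$pattern %in% c("perfectly_congruent", "weakly_congruent",
                             "consistent")) {
    qual <- if (verdict$hs_optimal_affordable)
      "is efficient and affordable from the patient perspective"
    else "is efficient from the patient perspective but not affordable"
    lines <- c(lines, sprintf("  %s %s.", verdict$hs_optimal, qual))
  }
  c(lines, sprintf("  Next steps: %s", verdict$recommendation))
}
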