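# End-to-end orchestration: config -> cohorts -> ICER tables -> PSA/CEAC ->
# affordability -> congruence verdict, with a run manifest and CSV outputs.

.base_case_points <- function(params, strategies, run, n, seed) {
  rows <- lapply(strategies, function(s) {
    co <- simulate_cohort(params, s, run, seed = seed, n = n)
    m <- co$summary$mean
    se <- co$summary$se
    data.frame(strategy = s$id,
               cost_patient = m[["cost_patient_disc"]],
               cost_hs = m[["cost_hs_disc"]],
               dalys = m[["dalys_disc"]],
               years_on_art = m[["years_on_art"]],
               survival_years = m[["survival_years"]],
               se_cost_patient = se[["cost_patient_disc"]],
               se_cost_hs = se[["cost_hs_disc"]],
               se_dalys = se[["dalys_disc"]])
  })
  do.call(rbind, rows)
}

# DALYs averted relative to the highest-burden arm, so effects are
# nonnegative; incremental comparisons are invariant to this common shift.
.averted <- function(dalys) max(dalys) - dalys

.warn_close_calls <- function(tab, se_cost, se_eff) {
  f <- which(tab$status %in% c("reference", "nondominated"))
  if (length(f) < 2) return(invisible())
  for (i in f[-1]) {
    dc <- abs(tab$inc_cost[i])
    de <- abs(tab$inc_effect[i])
    se_c <- 2 * sqrt(se_cost[tab$strategy[i]]^2 +
                       se_cost[tab$strategy[f[match(i, f) - 1]]]^2)
    se_e <- 2 * sqrt(se_eff[tab$strategy[i]]^2 +
                       se_eff[tab$strategy[f[match(i, f) - 1]]]^2)
    if (dc < se_c || de < se_e)
      warning("frontier step into '", tab$strategy[i],
              "' is within 2 Monte Carlo SE; ordering is uncertain",
              call. = FALSE)
  }
  invisible()
}

#' Run the full multi-perspective analysis
#'
#' Loads (or accepts) a configuration, simulates every strategy once under
#' both perspectives, builds both ICER tables, runs the PSA and acceptability
#' curves, annualizes patient costs for the affordability table, classifies
#' perspective congruence and renders the report. All randomness flows from
#' one master seed.
#'
#' @param config Path to a YAML config or a `perspecta_config`.
#' @param scale Scale factor dividing `n_individuals` and `psa_draws` for
#'   desk-scale runs (e.g. `0.05` turns 200,000 persons / 1000 draws into
#'   10,000 / 50).
#' @param seed Master seed override.
#' @param outdir Optional output directory; when given, writes
#'   `icer_patient.csv`, `icer_health_sector.csv`, `ceac_patient.csv`,
#'   `ceac_health_sector.csv`, `affordability.csv`, `psa_draws.csv`,
#'   `verdict.txt` and `manifest.json`.
#' @param psa Set `FALSE` to skip the PSA/CEAC stage.
#' @return List with `base` (per-strategy means), `icer` (patient and
#'   health-sector `perspecta_icer`), `ceac` (both perspectives),
#'   `affordability`, `verdict`, `report` (text lines), `psa` (draw-level
#'   results) and `manifest`.
#' @export
run_full_analysis <- function(config, scale = 1, seed = NULL, outdir = NULL,
                              psa = TRUE) {
  cfg <- if (inherits(config, "perspecta_config")) config
         else load_config(config)
  params <- cfg$params
  run <- cfg$run
  if (!is.null(seed)) run$seed <- as.integer(seed)
  if (!is.numeric(scale) || scale <= 0 || scale > 1)
    stop("stage config: scale must be in (0, 1]")
  n <- max(1L, as.integer(round(run$n_individuals * scale)))
  draws <- max(2L, as.integer(round(run$psa_draws * scale)))
  lambda <- run$wtp_threshold %||% (0.3 * pv(params, "gdp_pc"))
  threshold <- run$affordability_threshold %||%
    pv(params, "oop_health_expenditure_annual")
  d <- pv(params, "discount_rate")

  message(sprintf("[simulate] n = %d persons x %d strategies, seed %d",
                  n, length(cfg$strategies), run$seed))
  base <- .base_case_points(params, cfg$strategies, run, n, run$seed)
  effect <- .averted(base$dalys)
  icer_pat <- build_icer_table(data.frame(strategy = base$strategy,
                                          cost = base$cost_patient,
                                          effect = effect))
  icer_hs <- build_icer_table(data.frame(strategy = base$strategy,
                                         cost = base$cost_hs,
                                         effect = effect))
  se_eff <- setNames(base$se_dalys, base$strategy)
  .warn_close_calls(icer_pat, setNames(base$se_cost_patient, base$strategy),
                    se_eff)
  .warn_close_calls(icer_hs, setNames(base$se_cost_hs, base$strategy),
                    se_eff)

  ann <- annualize_cost(base$cost_patient, base$years_on_art, d)
  aff_all <- affordability_check(ann, threshold)
  affordability <- data.frame(strategy = base$strategy,
                              lifetime_cost = base$cost_patient,
                              years_on_art = base$years_on_art,
                              annual_cost = ann,
                              ratio = aff_all$ratio,
                              affordable = aff_all$affordable)

  hs_opt <- optimal_at_wtp(icer_hs, lambda)
  aff_opt <- affordability_check(
    affordability$annual_cost[affordability$strategy == hs_opt], threshold)
  verdict <- classify_alignment(icer_hs, icer_pat, lambda, aff_opt)
  report <- render_report(verdict, icer_hs, icer_pat, affordability)

  ceac <- NULL
  psa_df <- NULL
  if (psa) {
    message(sprintf("[psa] %d draws x %d persons, seed %d",
                    draws, run$psa_n_individuals, run$seed))
    psa_df <- run_psa(params, cfg$strategies, run, seed = run$seed,
                      draws = draws)
    mk <- function(cost_col) {
      pts <- data.frame(draw = psa_df$draw, strategy = psa_df$strategy,
                        cost = psa_df[[cost_col]], effect = -psa_df$dalys)
      compute_ceac(pts, run$wtp_grid)
    }
    ceac <- list(patient = mk("cost_patient"), health_sector = mk("cost_hs"))
  }

  manifest <- list(
    package = "perspecta",
    version = as.character(packageVersion("perspecta")),
    created_utc = format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    config_md5 = if (is.character(config))
      unname(tools::md5sum(config)) else NA_character_,
    seed = run$seed, n_individuals = n, psa_draws = if (psa) draws else 0L,
    psa_n_individuals = run$psa_n_individuals, scale = scale,
    horizon_years = run$horizon_years,
    wtp_threshold = lambda, affordability_threshold = threshold,
    strategies = vapply(cfg$strategies, function(s) s$id, ""))

  out <- list(base = base, icer = list(patient = icer_pat,
                                       health_sector = icer_hs),
              ceac = ceac, affordability = affordability, verdict = verdict,
              report = report, psa = psa_df, manifest = manifest)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    paths <- c(icer_patient = "icer_patient.csv",
               icer_health_sector = "icer_health_sector.csv",
               affordability = "affordability.csv",
               verdict = "verdict.txt", manifest = "manifest.json")
    write.csv(as.data.frame(icer_pat),
              file.path(outdir, "icer_patient.csv"), row.names = FALSE)
    write.csv(as.data.frame(icer_hs),
              file.path(outdir, "icer_health_sector.csv"), row.names = FALSE)
    write.csv(affordability, file.path(outdir, "affordability.csv"),
              row.names = FALSE)
    if (psa) {
      write.csv(as.data.frame(ceac$patient),
                file.path(outdir, "ceac_patient.csv"), row.names = FALSE)
      write.csv(as.data.frame(ceac$health_sector),
                file.path(outdir, "ceac_health_sector.csv"),
                row.names = FALSE)
      write.csv(psa_df, file.path(outdir, "psa_draws.csv"),
                row.names = FALSE)
      paths <- c(paths, ceac_patient = "ceac_patient.csv",
                 ceac_health_sector = "ceac_health_sector.csv",
                 psa_draws = "psa_draws.csv")
    }
    writeLines(report, file.path(outdir, "verdict.txt"))
    manifest$outputs <- as.list(paths)
    out$manifest <- manifest
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    message("[done] outputs written to ", outdir)
  }
  invisible(out)
}
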