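#' Published reference results for the Mozambique case study
#'
#' The per-person lifetime results of the full-scale (200,000 person,
#' 1000-draw) analysis as published for the six strategies under each
#' perspective: discounted total cost, DALYs averted, mean survival, mean
#' years on ART and the equivalent annual cost while on ART. These printed
#' values are inputs for the deterministic analytics (ICER ladder,
#' annualization, affordability, congruence classification) and for
#' validating this package's re-implementation.
#'
#' @param perspective Optionally filter to `"patient"` or `"health_sector"`.
#' @return data.frame with columns `perspective`, `strategy`, `total_cost`,
#'   `dalys_averted`, `survival_years`, `years_on_art`,
#'   `annual_cost_on_art`.
#' @export
reference_results <- function(perspective = NULL) {
  path <- system.file("extdata", "mozambique_reference_results.csv",
                      package = "perspecta")
  out <- read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(perspective)) {
    perspective <- match.arg(perspective, c("patient", "health_sector"))
    out <- out[out$perspective == perspective, , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}
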