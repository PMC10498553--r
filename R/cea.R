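# Efficiency frontier / ICER analytics, acceptability curves, and
# annuity-based affordability.

#' Build an ICER table with dominance analysis
#'
#' Sorts strategies by mean cost (ties broken by effect, descending), removes
#' strictly dominated strategies (costlier and no more effective), then
#' iteratively removes extendedly dominated strategies (whose ICER meets or
#' exceeds the ICER of the next more effective option), and computes ICERs
#' along the remaining frontier. Every row's incremental cost and effect are
#' reported against the previous non-dominated strategy in cost order (the
#' convention of published league tables); ICERs are only defined for
#' frontier rows. The cheapest frontier strategy is the reference.
#'
#' @param points data.frame with columns `strategy`, `cost`, `effect`
#'   (effect = health gain, e.g. DALYs averted; any common baseline shift is
#'   immaterial).
#' @return A `perspecta_icer` data.frame with columns `strategy`, `cost`,
#'   `effect`, `status` (`reference`, `nondominated`, `strictly_dominated`,
#'   `extendedly_dominated`), `inc_cost`, `inc_effect`, `icer`.
#' @examples
#' build_icer_table(data.frame(strategy = c("A", "B", "C"),
#'                             cost = c(0, 10, 12), effect = c(0, 1, 3)))
#' @export
build_icer_table <- function(points) {
  stopifnot(is.data.frame(points),
            all(c("strategy", "cost", "effect") %in% names(points)))
  if (nrow(points) < 1) stop("need at least one strategy")
  if (anyDuplicated(points$strategy)) stop("duplicate strategy ids")
  if (!all(is.finite(points$cost)) || !all(is.finite(points$effect)))
    stop("costs and effects must be finite")
  tab <- points[order(points$cost, -points$effect), , drop = FALSE]
  rownames(tab) <- NULL
  n <- nrow(tab)
  tab$status <- "nondominated"
  # strict dominance: anything no more effective than a cheaper option
  best <- -Inf
  for (i in seq_len(n)) {
    if (tab$effect[i] <= best && i > 1) {
      tab$status[i] <- "strictly_dominated"
    } else {
      best <- max(best, tab$effect[i])
    }
  }
  # extended dominance: remove options whose ICER >= the next step's ICER
  repeat {
    cand <- which(tab$status == "nondominated")
    if (length(cand) <= 2) break
    ic <- diff(tab$cost[cand]) / diff(tab$effect[cand])
    drop <- which(ic[-length(ic)] >= ic[-1])
    if (!length(drop)) break
    tab$status[cand[drop[1] + 1L]] <- "extendedly_dominated"
  }
  frontier <- which(tab$status == "nondominated")
  tab$status[frontier[1]] <- "reference"
  tab$inc_cost <- NA_real_
  tab$inc_effect <- NA_real_
  tab$icer <- NA_real_
  last_nd <- NA_integer_
  for (i in seq_len(n)) {
    nd <- tab$status[i] %in% c("reference", "nondominated")
    if (!is.na(last_nd)) {
      tab$inc_cost[i] <- tab$cost[i] - tab$cost[last_nd]
      tab$inc_effect[i] <- tab$effect[i] - tab$effect[last_nd]
      if (nd) tab$icer[i] <- tab$inc_cost[i] / tab$inc_effect[i]
    }
    if (nd) last_nd <- i
  }
  class(tab) <- c("perspecta_icer", "data.frame")
  tab
}

#' Frontier (non-dominated) strategies of an ICER table
#'
#' @param table A `perspecta_icer`.
#' @return Character vector of strategy ids on the efficiency frontier.
#' @export
frontier_strategies <- function(table) {
  stopifnot(inherits(table, "perspecta_icer"))
  table$strategy[table$status %in% c("reference", "nondominated")]
}

#' Optimal strategy at a willingness-to-pay threshold
#'
#' The frontier strategy with the largest ICER not exceeding `lambda` (the
#' reference if none); equivalent to maximizing net monetary benefit
#' `lambda * effect - cost` over all strategies, with ties broken toward the
#' cheaper strategy.
#'
#' @param table A `perspecta_icer`.
#' @param lambda Willingness to pay, USD per unit of effect; >= 0.
#' @return Strategy id.
#' @export
optimal_at_wtp <- function(table, lambda) {
  stopifnot(inherits(table, "perspecta_icer"), nrow(table) >= 1)
  if (!is.finite(lambda) || lambda < 0)
    stop("lambda must be a nonnegative number")
  f <- table[table$status %in% c("reference", "nondominated"), ]
  ic <- f$icer
  ic[1] <- -Inf
  f$strategy[max(which(ic <= lambda))]
}

#' Present-value annuity factor
#'
#' `(1 - (1 + d)^(-Y)) / d`, with the limit `Y` as `d -> 0`.
#'
#' @param d Annual discount rate, >= 0.
#' @param Y Duration in years, > 0.
#' @return Annuity factor in years.
#' @export
annuity_factor <- function(d, Y) {
  if (any(d < 0)) stop("discount rate must be nonnegative")
  if (any(Y <= 0)) stop("duration must be positive")
  len <- max(length(d), length(Y))
  d <- rep_len(d, len)
  Y <- rep_len(Y, len)
  ifelse(d == 0, Y, (1 - (1 + d)^(-Y)) / d)
}

#' Equivalent annual cost
#'
#' Converts a discounted lifetime cost `C_T` into the constant annual stream
#' `C_A = C_T / annuity_factor(d, Y_T)` paid over the `Y_T` years a person
#' spends on treatment.
#'
#' @param C_T Discounted total cost, USD, >= 0.
#' @param Y_T Average years on treatment, > 0.
#' @param d Annual discount rate.
#' @return Equivalent annual cost, USD per year.
#' @examples
#' annualize_cost(26.82, 22.5, 0.05)  # 2.01
#' @export
annualize_cost <- function(C_T, Y_T, d) {
  if (any(C_T < 0)) stop("C_T must be nonnegative")
  C_T / annuity_factor(d, Y_T)
}

#' Affordability check against an annual threshold
#'
#' @param C_A Equivalent annual cost, USD per year.
#' @param threshold Affordability threshold, USD per year, > 0 (e.g. average
#'   annual out-of-pocket health expenditure).
#' @return List with `affordable` (boundary inclusive: `C_A <= threshold`)
#'   and `ratio = C_A / threshold`.
#' @examples
#' affordability_check(9.83, 4.14)  # unaffordable, ratio 2.374
#' @export
affordability_check <- function(C_A, threshold) {
  if (!all(is.finite(threshold)) || any(threshold <= 0))
    stop("threshold must be positive")
  list(affordable = C_A <= threshold, ratio = C_A / threshold)
}

#' Cost-effectiveness acceptability curves
#'
#' For each willingness-to-pay value and each PSA draw, the strategy
#' maximizing net monetary benefit (ties toward the cheaper strategy) gets
#' one vote; the CEAC is each strategy's vote share across draws.
#'
#' @param psa_results data.frame with columns `draw`, `strategy`, `cost`,
#'   `effect`; every strategy must appear in every draw.
#' @param wtp_grid Strictly increasing willingness-to-pay grid.
#' @return A `perspecta_ceac` data.frame: one row per (wtp, strategy) with
#'   `prob_optimal`.
#' @export
compute_ceac <- function(psa_results, wtp_grid) {
  stopifnot(is.data.frame(psa_results),
            all(c("draw", "strategy", "cost", "effect") %in%
                  names(psa_results)))
  if (length(wtp_grid) < 1) stop("wtp_grid must be nonempty")
  if (any(diff(wtp_grid) <= 0)) stop("wtp_grid must be strictly increasing")
  draws <- split(psa_results, psa_results$draw)
  strategies <- sort(unique(psa_results$strategy))
  for (dd in draws) {
    if (!setequal(dd$strategy, strategies))
      stop("every strategy must be present in every draw")
  }
  votes <- matrix(0, length(wtp_grid), length(strategies),
                  dimnames = list(NULL, strategies))
  for (dd in draws) {
    dd <- dd[order(dd$cost), ]
    for (j in seq_along(wtp_grid)) {
      nmb <- wtp_grid[j] * dd$effect - dd$cost
      win <- dd$strategy[which.max(nmb)]  # first max = cheapest on ties
      votes[j, win] <- votes[j, win] + 1
    }
  }
  probs <- votes / length(draws)
  out <- data.frame(wtp = rep(wtp_grid, times = length(strategies)),
                    strategy = rep(strategies, each = length(wtp_grid)),
                    prob_optimal = as.vector(probs))
  class(out) <- c("perspecta_ceac", "data.frame")
  out
}

#' Willingness-to-pay values where the modal-optimal strategy changes
#'
#' @param ceac A `perspecta_ceac`.
#' @return data.frame with `from`, `to` (strategy ids) and `wtp_low`,
#'   `wtp_high` bracketing each modal switch on the grid.
#' @export
ceac_modal_switches <- function(ceac) {
  stopifnot(inherits(ceac, "perspecta_ceac"))
  wtp <- sort(unique(ceac$wtp))
  modal <- vapply(wtp, function(l) {
    sub <- ceac[ceac$wtp == l, ]
    sub$strategy[which.max(sub$prob_optimal)]
  }, "")
  ch <- which(modal[-1] != modal[-length(modal)])
  data.frame(from = modal[ch], to = modal[ch + 1],
             wtp_low = wtp[ch], wtp_high = wtp[ch + 1])
}

#' @export
print.perspecta_icer <- function(x, digits = 2, ...) {
  cat("Efficiency frontier / ICER table\n")
  y <- as.data.frame(x)
  y$icer <- ifelse(is.na(y$icer) &
                     grepl("dominated", y$status), "(dominated)",
                   ifelse(is.na(y$icer), "reference",
                          format(round(y$icer, digits))))
  print(y, row.names = FALSE)
  invisible(x)
}
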