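test_that("the published league tables reproduce their ICERs and dominance", {
  # health-sector block: 1-month strictly dominated; frontier ICERs
  hs <- build_icer_table(reference_points("health_sector"))
  expect_equal(hs$status[hs$strategy == "clinical_1m"], "strictly_dominated")
  f <- hs[hs$status %in% c("reference", "nondominated"), ]
  expect_equal(f$strategy, c("clinical_3m", "clinical_6m",
                             "mixed_6m_community_3m", "community_3m",
                             "clinical_3m_case_mgmt"))
  expect_equal(round(f$icer[-1]), c(130, 1590, 1600, 17358))

  # patient block: status quo and 1-month dominated
  pat <- build_icer_table(reference_points("patient"))
  expect_equal(pat$status[pat$strategy == "clinical_1m"],
               "strictly_dominated")
  expect_equal(pat$status[pat$strategy == "clinical_3m"],
               "strictly_dominated")
  fp <- pat[pat$status %in% c("reference", "nondominated"), ]
  expect_equal(fp$strategy, c("clinical_6m", "mixed_6m_community_3m",
                              "community_3m", "clinical_3m_case_mgmt"))
  expect_equal(round(fp$icer[-1], 2), c(2.71, 2.89, 112.28))
  # dominated rows report increments vs the previous non-dominated row
  expect_equal(pat$inc_cost[pat$strategy == "clinical_3m"], 33.49 - 26.82)
  expect_equal(pat$inc_effect[pat$strategy == "clinical_3m"], 9.86 - 11.74)
})

test_that("extended dominance removes inside points", {
  tab <- build_icer_table(data.frame(strategy = c("A", "B", "C"),
                                     cost = c(0, 10, 12),
                                     effect = c(0, 1, 3)))
  expect_equal(tab$status, c("reference", "extendedly_dominated",
                             "nondominated"))
  expect_equal(tab$icer[3], 4)
  expect_error(build_icer_table(
    data.frame(strategy = c("A", "A"), cost = 1:2, effect = 1:2)),
    "duplicate")
})

test_that("frontier ICERs are strictly increasing on random instances", {
  set.seed(403)
  for (i in 1:200) {
    k <- sample(2:8, 1)
    pts <- data.frame(strategy = paste0("s", 1:k),
                      cost = runif(k, 0, 100), effect = runif(k, 0, 10))
    tab <- build_icer_table(pts)
    ic <- tab$icer[tab$status %in% c("reference", "nondominated")][-1]
    if (length(ic) > 1) expect_true(all(diff(ic) > 0))
    expect_true(all(ic > 0))
  }
})

test_that("optimal_at_wtp equals brute-force NMB maximization", {
  # the published tables at the 0.3 x GDPpc threshold
  lambda <- 0.3 * 467
  hs <- build_icer_table(reference_points("health_sector"))
  expect_equal(optimal_at_wtp(hs, lambda), "clinical_6m")
  pat <- build_icer_table(reference_points("patient"))
  expect_equal(optimal_at_wtp(pat, lambda), "clinical_3m_case_mgmt")
  expect_equal(optimal_at_wtp(hs, 0), "clinical_3m")

  # oracle: argmax of lambda * effect - cost over all strategies
  set.seed(404)
  for (i in 1:1000) {
    k <- sample(2:8, 1)
    pts <- data.frame(strategy = paste0("s", 1:k),
                      cost = runif(k, 0, 100), effect = runif(k, 0, 10))
    tab <- build_icer_table(pts)
    for (lam in c(0, runif(19, 0, 60))) {
      nmb <- lam * pts$effect - pts$cost
      oracle <- pts$strategy[order(-nmb, pts$cost)][1]
      expect_identical(optimal_at_wtp(tab, lam), oracle)
    }
  }
})

test_that("annualization reproduces the published annual costs", {
  # exactly reconstructible rows
  expect_equal(round(annualize_cost(26.82, 22.5, 0.05), 2), 2.01)
  expect_equal(round(annualize_cost(25.29, 19.2, 0.05), 2), 2.08)
  expect_equal(annualize_cost(10, 5, 0), 2)
  # round-trip identity and zero-discount limit
  set.seed(405)
  for (i in 1:100) {
    d <- runif(1, 0, 0.15)
    Y <- runif(1, 0.5, 60)
    x <- runif(1, 0, 500)
    A <- annuity_factor(d, Y)
    expect_equal(annualize_cost(A * x, Y, d), x, tolerance = 1e-9)
  }
  expect_equal(annuity_factor(0, 7), 7)
  expect_error(annualize_cost(10, 0, 0.05), "positive")
  # vectorized over strategies
  expect_equal(annualize_cost(c(26.82, 25.29), c(22.5, 19.2), 0.05),
               c(annualize_cost(26.82, 22.5, 0.05),
                 annualize_cost(25.29, 19.2, 0.05)))
})

test_that("affordability ratios match the published percentages", {
  a <- affordability_check(9.83, 4.14)
  expect_false(a$affordable)
  expect_equal(round(100 * a$ratio), 237)
  b <- affordability_check(2.01, 4.14)
  expect_true(b$affordable)
  expect_equal(round(100 * b$ratio), 49)
  # boundary inclusive
  expect_true(affordability_check(4.14, 4.14)$affordable)
  expect_error(affordability_check(1, 0), "positive")
  # published affordable/unaffordable calls for all six strategies
  ref <- reference_results("patient")
  calls <- affordability_check(ref$annual_cost_on_art, 4.14)$affordable
  expect_identical(setNames(calls, ref$strategy),
                   c(clinical_6m = TRUE, mixed_6m_community_3m = TRUE,
                     community_3m = TRUE, clinical_3m = TRUE,
                     clinical_3m_case_mgmt = TRUE, clinical_1m = FALSE))
})

test_that("CEAC vote shares sum to one and step at the pairwise ICER", {
  # single strategy: probability one everywhere
  one <- data.frame(draw = 1:3, strategy = "only", cost = 1, effect = 1)
  ceac <- compute_ceac(one, c(0, 1, 2))
  expect_true(all(ceac$prob_optimal == 1))
  # two strategies, degenerate draws: step function at their ICER (= 5)
  two <- do.call(rbind, lapply(1:4, function(d)
    data.frame(draw = d, strategy = c("cheap", "eff"),
               cost = c(0, 10), effect = c(0, 2))))
  grid <- c(1, 4.9, 5.1, 20)
  ceac <- compute_ceac(two, grid)
  cheap <- ceac[ceac$strategy == "cheap", "prob_optimal"]
  expect_equal(cheap, c(1, 1, 0, 0))
  # shares sum to one at every grid point (random PSA-like input)
  set.seed(406)
  psa <- do.call(rbind, lapply(1:25, function(d)
    data.frame(draw = d, strategy = paste0("s", 1:5),
               cost = runif(5, 0, 100), effect = runif(5, 0, 10))))
  ceac <- compute_ceac(psa, seq(0, 50, by = 5))
  sums <- as.vector(tapply(ceac$prob_optimal, ceac$wtp, sum))
  expect_equal(sums, rep(1, length(sums)), tolerance = 1e-9)
  expect_error(compute_ceac(psa, numeric(0)), "nonempty")
  expect_error(compute_ceac(psa[psa$strategy != "s1" | psa$draw != 3, ],
                            c(0, 1)), "every draw")
})

test_that("ceac_modal_switches finds the crossover", {
  two <- do.call(rbind, lapply(1:4, function(d)
    data.frame(draw = d, strategy = c("cheap", "eff"),
               cost = c(0, 10), effect = c(0, 2))))
  sw <- ceac_modal_switches(compute_ceac(two, c(1, 4.9, 5.1, 20)))
  expect_equal(nrow(sw), 1)
  expect_equal(sw$from, "cheap")
  expect_equal(sw$to, "eff")
  expect_equal(sw$wtp_low, 4.9)
  expect_equal(sw$wtp_high, 5.1)
})
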