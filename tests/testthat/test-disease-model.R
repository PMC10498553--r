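test_that("rate and risk conversions match their closed forms", {
  expect_equal(rate_to_monthly_prob(0), 0)
  expect_equal(rate_to_monthly_prob(21.2), 0.01751152606, tolerance = 1e-9)
  expect_equal(rate_to_monthly_prob(5.1), 0.004240981531, tolerance = 1e-9)
  expect_error(rate_to_monthly_prob(-1), "nonnegative")

  expect_equal(risk_to_monthly_prob(0, 12), 0)
  expect_equal(risk_to_monthly_prob(0.20, 12), 0.01842347013,
               tolerance = 1e-9)
  expect_equal(risk_to_monthly_prob(0.371, 12), 0.03789851026,
               tolerance = 1e-9)
  expect_error(risk_to_monthly_prob(1, 12), "infinite hazard")
})

test_that("monthly probabilities compound back to their source risks", {
  set.seed(402)
  for (i in 1:200) {
    P <- runif(1, 0, 0.95)
    m <- sample(c(1, 3, 6, 12, 24), 1)
    p <- risk_to_monthly_prob(P, m)
    expect_equal(1 - (1 - p)^m, P, tolerance = 1e-9)
    r <- runif(1, 0, 60)
    expect_equal(-1200 * log(1 - rate_to_monthly_prob(r)), r,
                 tolerance = 1e-9)
  }
})

test_that("odds-ratio adjustment matches hand computation and is monotone", {
  expect_equal(apply_odds_ratio(0.36, 1.0), 0.36)
  expect_equal(apply_odds_ratio(0.5, 2.0), 2 / 3)
  # 0.36 is the 2-year compounding of the 20% 12-month risk
  expect_equal(1 - (1 - 0.20)^2, 0.36)
  expect_equal(apply_odds_ratio(0.36, 0.41), 0.187404774, tolerance = 1e-9)
  ors <- seq(0.1, 3, by = 0.1)
  expect_true(all(diff(apply_odds_ratio(0.36, ors)) > 0))
  expect_error(apply_odds_ratio(0, 2), "strictly inside")
  expect_error(apply_odds_ratio(0.3, 0), "positive")
})

test_that("CD4 drift converts to band-crossing probabilities by width", {
  expect_equal(cd4_band_transition_probs(0, "gt500")$prob, 0)
  down <- cd4_band_transition_probs(-60, "c350_500")
  expect_equal(down$prob, 0.03333333333, tolerance = 1e-9)
  expect_equal(down$direction, "down")
  up <- cd4_band_transition_probs(205, "c200_349")
  expect_equal(up$prob, 0.1138888889, tolerance = 1e-9)
  expect_equal(up$direction, "up")
  # lt200 is 200 cells wide
  expect_equal(cd4_band_transition_probs(-60, "lt200")$prob, 60 / 2400)
  expect_error(cd4_band_transition_probs(10, "cd4_900"), "unknown")
})

test_that("transition model composes the conversions on the packaged set", {
  cfg <- moz()
  m1 <- build_transition_model(cfg$params, clinic_1m())
  expect_equal(unname(m1$p_death["lt200"]), 0.01751152606, tolerance = 1e-9)
  expect_equal(m1$p_ltfu_regular, risk_to_monthly_prob(0.20, 12))
  m6 <- build_transition_model(
    cfg$params, strategy_definition("clinical_6m", 6L, "clinic"))
  expect_equal(m6$p_ltfu_regular,
               risk_to_monthly_prob(apply_odds_ratio(0.36, 0.41), 24),
               tolerance = 1e-12)
  mc <- build_transition_model(
    cfg$params, strategy_definition("community_3m", 3L, "community"))
  expect_equal(mc$p_ltfu_regular, rate_to_monthly_prob(5.1))
  # tracing swaps the re-engagement probability
  mt <- build_transition_model(
    cfg$params, strategy_definition("x", 3L, "clinic", tracing_enabled = TRUE))
  expect_equal(mt$p_reengage, risk_to_monthly_prob(0.371, 12))
  # mixed builds one model per arm
  mm <- build_transition_model(
    cfg$params, strategy_definition("mix", 6L, "mixed",
                                    mixed_allocation = 0.5))
  expect_s3_class(mm, "perspecta_tmodel_mixed")
  expect_length(mm$arms, 2)
  expect_equal(mm$arms[[1]]$model$p_ltfu_regular, m6$p_ltfu_regular)
})

test_that("LTFU hazards order 1-month > 3-month > 6-month", {
  check <- function(params) {
    h <- vapply(c(1L, 3L, 6L), function(k) {
      build_transition_model(
        params, strategy_definition(paste0("c", k), k, "clinic")
      )$p_ltfu_regular
    }, numeric(1))
    expect_true(h[1] > h[2] && h[2] > h[3])
  }
  check(moz()$params)
  for (seed in 1:20) check(make_fixture(seed)$params)
})

test_that("zeroed hazards leave only CD4 and line transitions", {
  p <- degenerate_params()
  vals <- p$values
  vals$cd4_gain_on_art <- 205
  vals$annual_switch_risk_dtg <- 0.0025
  p <- parameter_set(vals)
  m <- build_transition_model(p, clinic_1m())
  expect_equal(unname(m$p_death), rep(0, 4))
  expect_equal(m$p_ltfu_regular, 0)
  dist <- transition_distribution(m, "c200_349", "on_first_line", 12)
  nonzero <- dist[dist > 0]
  expect_setequal(
    names(nonzero),
    c("switch_to_second_line_cd4_up", "switch_to_second_line_cd4_stay",
      "remain_first_line_cd4_up", "remain_first_line_cd4_stay"))
})

test_that("per-state outgoing probability mass sums to one everywhere", {
  check_model <- function(params, strategy) {
    m <- build_transition_model(params, strategy)
    if (inherits(m, "perspecta_tmodel_mixed")) {
      for (a in m$arms) check_sums(a$model)
    } else {
      check_sums(m)
    }
  }
  check_sums <- function(m) {
    for (band in cd4_bands()) {
      for (care in c("on_first_line", "off_art_first_line_eligible",
                     "on_second_line", "off_art_second_line_only")) {
        for (moa in c(0, 12)) {
          for (failing in c(FALSE, TRUE)) {
            dist <- transition_distribution(m, band, care, moa, failing)
            expect_true(all(dist >= 0) && all(dist <= 1))
            expect_equal(sum(dist), 1, tolerance = 1e-9)
          }
        }
      }
    }
  }
  cfg <- moz()
  for (s in cfg$strategies) check_model(cfg$params, s)
  for (seed in 1:100) {
    f <- make_fixture(seed)
    check_model(f$params, f$strategies[[sample.int(6, 1)]])
  }
})

test_that("transition_table exports every state and sums to one per state", {
  m <- build_transition_model(moz()$params, clinic_1m())
  tab <- transition_table(m)
  expect_s3_class(tab, "data.frame")
  sums <- aggregate(prob ~ band + care + phase, tab, sum)
  expect_equal(sums$prob, rep(1, nrow(sums)), tolerance = 1e-9)
  expect_equal(nrow(sums), 4 * 4 * 2)
})
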