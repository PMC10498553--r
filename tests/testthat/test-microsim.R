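test_that("discounting matches closed forms including half-value time", {
  expect_equal(discount(100, 0, 0.05), 100)
  expect_equal(discount(100, 1, 0.05), 100 / 1.05)
  expect_equal(discount(1, log(2) / log(1.05), 0.05), 0.5, tolerance = 1e-12)
  expect_equal(discount(7, 3, 0), 7)
  expect_error(discount(1, 1, -0.1), "nonnegative")
})

test_that("DALY accrual is weight x time and additive over intervals", {
  params <- moz()$params
  expect_equal(accrue_daly("gt500", TRUE, params, 1), 0.078)
  expect_equal(accrue_daly("lt200", FALSE, params, 1), 0.58)
  expect_equal(accrue_daly("lt200", FALSE, degenerate_params(), 1), 0)
  # additivity over disjoint intervals
  expect_equal(accrue_daly("c200_349", TRUE, params, 0.3) +
                 accrue_daly("c200_349", TRUE, params, 0.7),
               accrue_daly("c200_349", TRUE, params, 1))
})

test_that("a degenerate no-event world gives horizon survival and zero accruals", {
  p <- degenerate_params()
  run <- run_config(n_individuals = 50L, horizon_years = 5, seed = 1,
                    psa_draws = 2L)
  co <- simulate_cohort(p, clinic_1m(), run)
  expect_true(all(co$person$survival_years == 5))
  expect_true(all(co$person$years_on_art == 5))
  expect_true(all(co$person$dalys_disc == 0))
  expect_true(all(co$person$cost_patient_disc == 0))
  expect_true(all(co$person$cost_hs_disc == 0))
})

test_that("engine equals the closed-form annuity under degenerate parameters", {
  cost <- 12.5
  p <- degenerate_params(monthly_cost = cost, daly_w = 0.2)
  horizon <- 8
  run <- run_config(n_individuals = 3L, horizon_years = horizon, seed = 2,
                    psa_draws = 2L)
  co <- simulate_cohort(p, clinic_1m(), run)
  T <- horizon * 12
  d <- p$values$discount_rate
  v <- (1 + d)^(-(seq_len(T) - 0.5) / 12)       # half-cycle midpoints
  expect_equal(co$person$cost_hs_undisc, rep(cost * T, 3), tolerance = 1e-9)
  expect_equal(co$person$cost_hs_disc, rep(cost * sum(v), 3),
               tolerance = 1e-9)
  expect_equal(co$person$dalys_disc, rep(0.2 / 12 * sum(v), 3),
               tolerance = 1e-9)
  # patient side sees the same discount weights through the visit schedule
  expect_equal(co$person$cost_patient_disc, rep(0, 3))
})

test_that("death-only world reproduces the exponential mean lifetime", {
  r_annual <- 50  # per 100 person-years -> mean lifetime 2 years
  p <- degenerate_params(mortality = r_annual)
  run <- run_config(n_individuals = 20000L, horizon_years = 60, seed = 3,
                    psa_draws = 2L)
  co <- simulate_cohort(p, clinic_1m(), run)
  surv <- co$person$survival_years
  se <- sd(surv) / sqrt(length(surv))
  expect_lt(abs(mean(surv) - 100 / r_annual), 3 * se)
  # years of life lost: weight one for every cycle not lived before the
  # horizon; the death cycle itself counts as lost but survival credits its
  # first half (half-cycle correction), hence the 1/24 offset for deaths
  died <- co$person$final_care == 0
  expect_true(all(co$person$dalys_undisc[died] > 0))
  expect_equal(co$person$dalys_undisc + surv,
               ifelse(died, 60 + 1 / 24, 60), tolerance = 1e-9)
})

test_that("simulation is reproducible and seed-sensitive", {
  cfg <- make_fixture(4, "tiny")
  s <- cfg$strategies[[6]]  # mixed: exercises arm splitting
  a <- simulate_cohort(cfg$params, s, cfg$run, seed = 10)
  b <- simulate_cohort(cfg$params, s, cfg$run, seed = 10)
  expect_identical(a$person, b$person)
  c2 <- simulate_cohort(cfg$params, s, cfg$run, seed = 11)
  expect_false(identical(a$person, c2$person))
  one <- simulate_person(cfg$params, s, cfg$run, seed = 10)
  expect_identical(nrow(one), 1L)
})

test_that("per-person invariants hold across fixtures", {
  for (seed in c(5, 6)) {
    cfg <- make_fixture(seed, "tiny")
    for (s in cfg$strategies[c(1, 5, 6)]) {
      co <- simulate_cohort(cfg$params, s, cfg$run)
      pr <- co$person
      expect_true(all(pr$cost_patient_disc <= pr$cost_patient_undisc + 1e-12))
      expect_true(all(pr$cost_hs_disc <= pr$cost_hs_undisc + 1e-12))
      expect_true(all(pr$dalys_disc <= pr$dalys_undisc + 1e-12))
      expect_true(all(pr$survival_years <= cfg$run$horizon_years + 1e-12))
      expect_true(all(pr$years_on_art <= pr$survival_years + 1e-12))
      expect_true(all(pr$cost_patient_disc >= 0) && all(pr$dalys_disc >= 0))
      m <- co$summary$mean
      for (nm in names(m))
        expect_true(m[[nm]] >= min(pr[[nm]]) && m[[nm]] <= max(pr[[nm]]))
    }
  }
})

test_that("means are stable when n doubles (within 3 combined SE)", {
  cfg <- make_fixture(7, "tiny")
  s <- cfg$strategies[[2]]
  a <- simulate_cohort(cfg$params, s, cfg$run, seed = 1, n = 1500)
  b <- simulate_cohort(cfg$params, s, cfg$run, seed = 2, n = 3000)
  for (nm in c("cost_patient_disc", "cost_hs_disc", "dalys_disc",
               "survival_years")) {
    tol <- 3 * sqrt(a$summary$se[[nm]]^2 + b$summary$se[[nm]]^2)
    expect_lt(abs(a$summary$mean[[nm]] - b$summary$mean[[nm]]), tol)
  }
})

test_that("lower LTFU hazard buys survival: 6-month beats 1-month refills", {
  cfg <- moz()
  run <- cfg$run
  s1 <- cfg$strategies[[1]]; s6 <- cfg$strategies[[3]]
  a <- simulate_cohort(cfg$params, s1, run, seed = 21, n = 20000)
  b <- simulate_cohort(cfg$params, s6, run, seed = 21, n = 20000)
  diff <- b$summary$mean[["survival_years"]] -
    a$summary$mean[["survival_years"]]
  se <- sqrt(a$summary$se[["survival_years"]]^2 +
               b$summary$se[["survival_years"]]^2)
  expect_gt(diff, 3 * se)
})

test_that("PSA runs are reproducible and carry every strategy per draw", {
  cfg <- make_fixture(8, "tiny")
  a <- run_psa(cfg$params, cfg$strategies, cfg$run, seed = 1, draws = 3,
               n = 100)
  b <- run_psa(cfg$params, cfg$strategies, cfg$run, seed = 1, draws = 3,
               n = 100)
  expect_identical(a, b)
  expect_equal(nrow(a), 3 * 6)
  expect_true(all(table(a$draw) == 6))
  expect_true(all(a$cost_patient >= 0) && all(a$dalys >= 0))
})
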