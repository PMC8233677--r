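test_that("population target follows constant-prevalence demographic growth", {
  p <- table1_defaults()
  expect_identical(population_target(p, 1), 1180553)
  # independent root-finding oracle for the calibrated rate
  r_oracle <- stats::uniroot(function(r) (1 + r)^29 - 1.2893, c(0, 0.05),
                             tol = 1e-14)$root
  expect_equal(calibrate_growth_rate(28.93, 29), 100 * r_oracle,
               tolerance = 1e-10)
  expect_equal(p$growth$rate, 100 * r_oracle, tolerance = 1e-10)
  expect_equal(population_target(p, 30), 1180553 * (1 + r_oracle)^29,
               tolerance = 1e-12)
  # zero growth: flat forever
  q <- inert_params(1180553)
  expect_equal(population_target(q, 30), 1180553)
  # explicit growth-factor series
  s <- toy_params()
  s$growth <- list(series = c(1.1, 1.2))
  expect_equal(population_target(s, 3), 3 * 1.1 * 1.2)
  expect_error(population_target(s, 4), "growth series")
  expect_error(population_target(p, 0), ">= 1")
})

test_that("initial allocation splits the population by entry shares", {
  p <- table1_defaults()
  s <- initial_allocation(p)
  expect_equal(s$year, 1L)
  # direct-multiplication oracle
  expect_equal(unname(s$stock),
               1180553 * c(20.71, 5.37, 2.42, 71.50) / 100)
  expect_equal(sum(s$stock), 1180553, tolerance = 1e-12)
  all_w <- initial_allocation(inert_params(500))
  expect_equal(unname(all_w$stock), c(0, 0, 0, 500))
})

test_that("year-1 outcome flows match direct arithmetic on start-of-year stocks", {
  p <- table1_defaults()
  o <- annual_outcomes(initial_allocation(p), p)
  stocks <- 1180553 * c(20.71, 5.37, 2.42, 71.50) / 100
  expect_equal(unname(o$deaths), stocks * c(0.77, 0.39, 0.53, 2.91) / 100)
  expect_equal(unname(o$abstinence_events), stocks * c(27, 26, 10, 1) / 100)
  expect_equal(o$heroin_transitions, stocks[4] * 1.5 / 100)
  z <- annual_outcomes(initial_allocation(inert_params()), inert_params())
  expect_equal(sum(z$deaths) + z$heroin_transitions +
                 sum(z$abstinence_events), 0)
  # mortality_scale multiplies deaths only
  p2 <- p
  p2$mortality_scale <- 0.5
  o2 <- annual_outcomes(initial_allocation(p2), p2)
  expect_equal(o2$deaths, o$deaths * 0.5)
  expect_equal(o2$abstinence_events, o$abstinence_events)
})

test_that("fixed-shares advancement rescales every stock by the growth factor", {
  p <- table1_defaults()
  s1 <- initial_allocation(p)
  s2 <- advance_fixed_shares(s1, p)
  expect_equal(s2$year, 2L)
  expect_equal(s2$stock, s1$stock * (1 + p$growth$rate / 100),
               tolerance = 1e-12)
  # zero growth is a steady state
  q <- inert_params()
  t1 <- initial_allocation(q)
  expect_equal(advance_fixed_shares(t1, q)$stock, t1$stock)
})

test_that("flow-based advancement reproduces the hand-worked toy ledger", {
  # 3 persons: MMT 1.5, UNTREATED 1.5; retention 50, deaths 10/20, phi_M 40,
  # heroin 10, zero growth. Year-end by hand:
  #   MMT deaths .15, stayers .75, discontinued .60
  #   W deaths .30, heroin .15, surviving pool 1.05 + .60 = 1.65
  #   entries: MMT .825, W .825; total 2.40; top-up .60 -> W 1.425
  p <- toy_params()
  s2 <- advance_flow_based(initial_allocation(p), p)
  expect_equal(unname(s2$stock), c(1.575, 0, 0, 1.425), tolerance = 1e-12)
  led <- attr(s2, "ledger")
  expect_equal(unname(led$deaths), c(0.15, 0, 0, 0.3), tolerance = 1e-12)
  expect_equal(led$heroin_transitions, 0.15, tolerance = 1e-12)
  expect_equal(unname(led$discontinued), c(0.6, 0, 0), tolerance = 1e-12)
  expect_equal(led$replenishment, 0.6, tolerance = 1e-12)
  # conservation: stocks(t+1) = stocks(t) - deaths - heroin + replenishment
  expect_equal(sum(s2$stock),
               3 - sum(led$deaths) - led$heroin_transitions +
                 led$replenishment, tolerance = 1e-12)
  expect_equal(sum(s2$stock), population_target(p, 2), tolerance = 1e-12)
})

test_that("a closed inert system is stationary under flow-based advancement", {
  q <- inert_params()
  traj <- run_scenario(q, 1, 5, "flow_based")
  for (t in 1:5) expect_equal(unname(traj$stocks[t, ]), c(0, 0, 0, 1000))
})

test_that("both advancement modes agree in year 1 and hold the prevalence line", {
  p <- table1_defaults()
  fx <- run_scenario(p, 1, 10, "fixed_shares")
  fl <- run_scenario(p, 1, 10, "flow_based")
  expect_equal(fx$stocks[1, ], fl$stocks[1, ])
  expect_equal(fx$deaths[1, ], fl$deaths[1, ])
  expect_equal(fx$heroin_transitions[1], fl$heroin_transitions[1])
  expect_equal(fx$abstinence_events[1, ], fl$abstinence_events[1, ])
  for (traj in list(fx, fl)) {
    expect_equal(traj$population,
                 vapply(1:10, function(t) population_target(p, t), 0),
                 tolerance = 1e-9)
  }
})

test_that("scenario runs compose coverage scaling with the annual cycle", {
  p <- table1_defaults()
  one <- run_scenario(p, 1, 1)
  expect_equal(one$horizon, 1L)
  expect_equal(round(one$heroin_transitions[1]), 12661)
  expect_error(run_scenario(p, 4), "infeasible")
  expect_error(run_scenario(p, 0), "> 0")
  expect_error(run_scenario(p, 1, 0), "horizon")
  quarter <- run_scenario(p, 0.25, 1)
  expect_equal(round_half_up(total_coverage(quarter$parameters), 2), 7.13)
})

test_that("tidy trajectory export carries all flows and round-trips via CSV", {
  p <- table1_defaults()
  traj <- run_scenario(p, 1.25, 5)
  tb <- tibble::as_tibble(traj)
  expect_equal(nrow(tb), 5 * 4)
  expect_equal(sum(tb$stock[tb$year == 3]), traj$population[3])
  expect_equal(sum(tb$heroin_transitions[tb$group != "UNTREATED"]), 0)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory_csv(traj, path)
  back <- read_trajectory_csv(path)
  expect_equal(back$stocks, traj$stocks, tolerance = 1e-9)
  expect_equal(back$deaths, traj$deaths, tolerance = 1e-9)
  expect_equal(back$heroin_transitions, traj$heroin_transitions,
               tolerance = 1e-9)
  expect_equal(back$mode, traj$mode)
})
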