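test_that("per-year contrasts do hand arithmetic with the stated sign convention", {
  base <- synthetic_trajectory(deaths = c(10, 10))
  alt <- synthetic_trajectory(deaths = c(11, 12))
  pc <- per_year_change(alt, base, "deaths")
  expect_equal(pc$abs_change, c(1, 2))
  expect_equal(pc$rel_change_pct, c(10, 20))
  # identity contrast
  self <- per_year_change(base, base, "deaths")
  expect_equal(self$abs_change, c(0, 0))
  expect_equal(self$rel_change_pct, c(0, 0))
  # zero baseline is flagged, not NaN-propagated
  z <- per_year_change(synthetic_trajectory(deaths = c(5, 5)),
                       synthetic_trajectory(deaths = c(0, 10)), "deaths")
  expect_false(z$rel_defined[1])
  expect_true(is.na(z$rel_change_pct[1]))
  expect_equal(z$rel_change_pct[2], -50)
})

test_that("comparisons refuse mismatched horizons and cross-mode pairs", {
  a <- synthetic_trajectory(deaths = 1:5)
  expect_error(per_year_change(a, synthetic_trajectory(deaths = 1:4), "deaths"),
               "horizon")
  b <- synthetic_trajectory(deaths = 1:5, mode = "flow_based")
  expect_error(per_year_change(a, b, "deaths"), "cross-mode")
})

test_that("swapping the arms negates absolute and maps relative changes to -x/(1+x)", {
  set.seed(42)
  for (i in 1:20) {
    a <- synthetic_trajectory(heroin = runif(8, 1, 100))
    b <- synthetic_trajectory(heroin = runif(8, 1, 100))
    fwd <- per_year_change(b, a, "heroin")
    rev <- per_year_change(a, b, "heroin")
    expect_equal(rev$abs_change, -fwd$abs_change)
    x <- fwd$rel_change_pct / 100
    expect_equal(rev$rel_change_pct / 100, -x / (1 + x), tolerance = 1e-12)
  }
})

test_that("the decade statistic sums relative changes and scales by ten", {
  base <- synthetic_trajectory(heroin = rep(100, 10))
  # constant 10% yearly relative change over a decade forces theta = 1
  up <- synthetic_trajectory(heroin = rep(110, 10))
  d <- decade_theta(up, base, "heroin", 1)
  expect_equal(d$theta, 1.0)
  expect_equal(d$percent, 10)
  expect_equal(d$cumulative, 100)
  # identical trajectories
  z <- decade_theta(base, base, "heroin", 1)
  expect_equal(z$theta, 0)
  expect_equal(z$cumulative, 0)
  # percent = theta * 10 and theta = sum of fractions on random series
  set.seed(7)
  a <- synthetic_trajectory(deaths = runif(30, 10, 50))
  b <- synthetic_trajectory(deaths = runif(30, 10, 50))
  for (dec in 1:3) {
    yrs <- (10 * (dec - 1) + 1):(10 * dec)
    s <- decade_theta(b, a, "deaths", dec)
    frac <- (outcome_series(b, "deaths")[yrs] -
               outcome_series(a, "deaths")[yrs]) /
      outcome_series(a, "deaths")[yrs]
    expect_equal(s$theta, sum(frac))
    expect_equal(s$percent, s$theta * 10)
  }
  expect_error(decade_theta(b, a, "deaths", 4), "outside horizon")
})

test_that("cumulative windows sum inclusively and add over disjoint windows", {
  traj <- synthetic_trajectory(abstinence = c(1, 2, 3, 4, 5))
  expect_equal(cumulative_window(traj, "abstinence", 3, 3), 3)
  expect_equal(cumulative_window(traj, "abstinence", 1, 5), 15)
  expect_equal(cumulative_window(traj, "abstinence", 1, 2) +
                 cumulative_window(traj, "abstinence", 3, 5),
               cumulative_window(traj, "abstinence", 1, 5))
  const <- synthetic_trajectory(deaths = rep(7, 6))
  expect_equal(cumulative_window(const, "deaths", 1, 6), 7 * 6)
  expect_error(cumulative_window(traj, "abstinence", 0, 3), "invalid window")
  expect_error(cumulative_window(traj, "abstinence", 2, 9), "invalid window")
  # zero growth + fixed shares: the decade total is ten times year 1
  p <- table1_defaults()
  p$growth$rate <- 0
  flat <- run_scenario(p, 1, 10)
  expect_equal(cumulative_window(flat, "deaths", 1, 10),
               10 * sum(flat$deaths[1, ]), tolerance = 1e-12)
})

test_that("the decade summary grid covers every outcome, decade, and scenario", {
  p <- table1_defaults()
  g <- decade_summary_grid(p, factors = c(1.25, 0.75), horizon = 30)
  expect_equal(nrow(g), 3 * 2 * 3)
  expect_setequal(unique(g$coverage_pct), c(35.63, 21.38))
  expect_equal(g$percent, g$theta * 10)
  # increased coverage lowers harms and raises abstinence in every decade
  up <- g[g$factor == 1.25, ]
  expect_true(all(up$cumulative[up$outcome != "abstinence"] < 0))
  expect_true(all(up$cumulative[up$outcome == "abstinence"] > 0))
})
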