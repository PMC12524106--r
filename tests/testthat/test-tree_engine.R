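test_that("branch probabilities follow the two-stage tree and conserve mass", {
  p <- branch_probabilities(vn$strategies$pitavastatin)
  expect_equal(unname(p), c(0.717, 0.283 * 0.796, 0.283 * 0.204))
  expect_equal(unname(p), c(0.717, 0.225268, 0.057732))

  # degenerate corners
  s1 <- strategy("sure", dose_arm("", 1, 1), dose_arm("", 1, 0.3))
  expect_equal(unname(branch_probabilities(s1)), c(1, 0, 0))
  s0 <- strategy("never", dose_arm("", 1, 0), dose_arm("", 1, 0))
  expect_equal(unname(branch_probabilities(s0)), c(0, 0, 1))

  # property sweep: conservation over a grid of (p1, p2)
  for (p1 in seq(0, 1, by = 0.1)) {
    for (p2 in seq(0, 1, by = 0.1)) {
      s <- strategy("x", dose_arm("", 1, p1), dose_arm("", 1, p2))
      expect_equal(sum(branch_probabilities(s)), 1, tolerance = 1e-12)
    }
  }
})

test_that("overall attainment matches the published per-strategy rates", {
  expect_equal(overall_attainment(0.759, 0.800), 0.9518)          # rosuvastatin
  expect_equal(round(overall_attainment(0.717, 0.796), 4), 0.9423) # pitavastatin
  expect_equal(round(overall_attainment(0.777, 0.817), 4), 0.9592) # atorvastatin
  expect_equal(overall_attainment(1, 0.123), 1)
  expect_equal(overall_attainment(0, 0.37), 0.37)
})

test_that("overall attainment is non-decreasing in p1 and p2", {
  grid <- seq(0, 1, by = 0.05)
  for (p2 in c(0, 0.3, 0.9)) {
    vals <- overall_attainment(grid, p2)
    expect_true(all(diff(vals) >= -1e-15))
  }
  for (p1 in c(0, 0.4, 0.95)) {
    vals <- overall_attainment(p1, grid)
    expect_true(all(diff(vals) >= -1e-15))
  }
})

test_that("the six fixture branch costs are reproduced exactly", {
  costs <- function(nm) vapply(
    c("ACHIEVE_INITIAL", "ACHIEVE_ESCALATED", "FAIL"),
    function(b) branch_cost(vn$strategies[[nm]], b, vn), numeric(1))
  expect_identical(unname(costs("pitavastatin")), c(69203400, 94582600, 94582600))
  expect_identical(unname(costs("atorvastatin")), c(81676910, 81786110, 81786110))
  expect_identical(unname(costs("rosuvastatin")), c(46095980, 74381230, 74381230))
})

test_that("branch costs decompose as drug-days plus panels plus downstream", {
  toy <- toy_scenario(downstream_branch_costs = c(ACHIEVE_INITIAL = 7, FAIL = 11))
  a <- toy$strategies$a
  # hand computation: horizon 10 d, escalation day 4, 2 tests x 10 per panel
  expect_equal(branch_cost(a, "ACHIEVE_INITIAL", toy), 100 * 10 + 1 * 2 * 10 + 7)
  expect_equal(branch_cost(a, "ACHIEVE_ESCALATED", toy), 100 * 4 + 200 * 6 + 2 * 2 * 10)
  expect_equal(branch_cost(a, "FAIL", toy), 100 * 4 + 200 * 6 + 2 * 2 * 10 + 11)

  free <- toy_scenario()
  free$strategies$a$initial$daily_price <- 0
  free$strategies$a$escalated$daily_price <- 0
  free$monitoring$test_unit_cost <- 0
  expect_equal(branch_cost(free$strategies$a, "ACHIEVE_INITIAL", free), 0)
  expect_equal(branch_cost(free$strategies$a, "FAIL", free), 0)
})

test_that("per-branch utility contributions multiply weight by probability", {
  u <- strategy_utility(vn$strategies$pitavastatin, vn)
  expect_equal(unname(u$contributions[["ACHIEVE_INITIAL"]]), 0.59188350)
  expect_equal(u$total, sum(u$contributions))

  # hand-evaluated atorvastatin total with the calibrated fail utility
  ua <- strategy_utility(vn$strategies$atorvastatin, vn)
  expect_equal(ua$total,
               0.8255 * (0.777 + 0.223 * 0.817) + 0.223 * 0.183 * vn$u_fail)
  expect_equal(ua$total, 0.82070086, tolerance = 1e-7)

  # equal weights collapse to a convex-combination identity
  flat <- toy_scenario()
  flat$u_base <- flat$u_fail <- 0.73
  expect_equal(strategy_utility(flat$strategies$a, flat)$total, 0.73)
})

test_that("total utility is bounded by the two weights and increasing in p1", {
  cfgs <- lapply(1:30, function(i) random_scenario(generator_spec(seed = i)))
  for (cfg in cfgs) {
    for (s in cfg$strategies) {
      tot <- strategy_utility(s, cfg)$total
      expect_gte(tot, cfg$u_fail - 1e-12)
      expect_lte(tot, cfg$u_base + 1e-12)
    }
  }
  # monotonicity in p1 at fixed p2, strict when u_base > u_fail
  base <- toy_scenario()
  tots <- vapply(seq(0, 0.9, by = 0.1), function(p1) {
    s <- strategy("x", dose_arm("", 1, p1), dose_arm("", 1, 0.5))
    strategy_utility(s, base)$total
  }, numeric(1))
  expect_true(all(diff(tots) > 0))
})

test_that("QALY multiplies utility by plain or annuity-discounted life years", {
  half <- toy_scenario(horizon_years = 14, days_per_year = 365,
                       escalation_day = 56)
  expect_equal(qaly(0.5, half), 7.0)
  expect_equal(qaly(0, half), 0)

  disc <- half
  disc$discount_mode <- "annual_annuity"
  disc$discount_rate <- 0.03
  expect_equal(qaly(1, disc), (1 - 1.03^-14) / 0.03)
  expect_equal(qaly(1, disc), 11.296073, tolerance = 1e-6)
})

test_that("annuity discounting converges to the undiscounted horizon as r -> 0", {
  cfg <- toy_scenario(horizon_years = 14, days_per_year = 365,
                      escalation_day = 56)
  cfg$discount_mode <- "annual_annuity"
  cfg$discount_rate <- 1e-10
  expect_equal(qaly(0.8255, cfg), 0.8255 * 14, tolerance = 1e-6)
  cfg$discount_rate <- 0
  expect_equal(qaly(0.8255, cfg), 0.8255 * 14)
})

test_that("evaluate_strategy assembles expected cost, utility, QALY and attainment", {
  r <- evaluate_strategy("pitavastatin", vn)
  expect_equal(r$expected_cost, 0.717 * 69203400 + 0.283 * 94582600)
  expect_equal(r$expected_cost, 76385713.6)
  expect_equal(r$qaly, r$total_utility * 14)
  expect_equal(r$lyg, 14)

  rr <- evaluate_strategy("rosuvastatin", vn)
  expect_equal(rr$overall_attainment, 0.9518)

  # p1 = 1 collapses to the no-escalation branch cost
  sure <- toy_scenario()
  sure$strategies$a$initial$p_attain <- 1
  rs <- evaluate_strategy("a", sure)
  expect_equal(rs$expected_cost, rs$branches$cost[1])
})

test_that("expected cost lies between the branch costs when no downstream costs", {
  for (i in 1:25) {
    cfg <- random_scenario(generator_spec(seed = 100 + i))
    for (nm in names(cfg$strategies)) {
      r <- evaluate_strategy(nm, cfg)
      expect_gte(r$expected_cost, min(r$branches$cost) - 1e-9)
      expect_lte(r$expected_cost, max(r$branches$cost) + 1e-9)
    }
  }
})

test_that("strategy_table summarises every strategy once", {
  tab <- strategy_table(evaluate_scenario(vn))
  expect_equal(tab$strategy, c("pitavastatin", "atorvastatin", "rosuvastatin"))
  expect_equal(tab$cost_no_escalation,
               c(69203400, 81676910, 46095980))
  expect_equal(tab$cost_escalation,
               c(94582600, 81786110, 74381230))
})
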