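test_that("incremental deltas reproduce the reported pairwise differences", {
  pit <- list(total_cost = 1062525311, total_qaly = 11.12292411)
  ato <- list(total_cost = 1093805451, total_qaly = 11.28300399)
  ros <- list(total_cost = 973277353, total_qaly = 11.19477268)

  d <- incremental(pit, ato)
  expect_equal(d$delta_cost, -31280140)
  expect_equal(d$delta_qaly, -0.16007988)

  d2 <- incremental(pit, ros)
  expect_equal(d2$delta_cost, 89247958)
  expect_equal(d2$delta_qaly, -0.07184857)

  same <- incremental(pit, pit)
  expect_equal(same$delta_cost, 0)
  expect_equal(same$delta_qaly, 0)
})

test_that("icer preserves sign and matches the two published headline ratios", {
  # reported integer ICERs; printed deltas carry limited precision, so the
  # recomputed ratios agree to well under one part in a million
  expect_equal(icer(-31280140, -0.16007988), 195403312, tolerance = 1e-6)
  expect_equal(icer(89247958, -0.07184857), -1242167485, tolerance = 1e-6)
  expect_equal(icer(0, 0.5), 0)
  expect_error(icer(10, 0), class = "cua_undefined_icer")
})

test_that("icer is antisymmetric in its arguments and scale-invariant", {
  dc <- -31280140; dq <- -0.16007988
  expect_equal(icer(-dc, -dq), icer(dc, dq))
  for (k in c(1e-6, 0.5, 3, 1e6)) {
    expect_equal(icer(k * dc, k * dq), icer(dc, dq))
  }
})

test_that("swapping intervention and comparator mirrors the comparison", {
  ab <- compare_strategies(vn, "pitavastatin", "rosuvastatin")
  ba <- compare_strategies(vn, "rosuvastatin", "pitavastatin")
  expect_equal(ab$delta_cost, -ba$delta_cost)
  expect_equal(ab$delta_qaly, -ba$delta_qaly)
  expect_equal(ab$icer, ba$icer)
  flip <- c(intervention_dominant = "comparator_dominant",
            comparator_dominant = "intervention_dominant",
            none = "none")
  expect_equal(unname(flip[ab$dominance]), ba$dominance)
})

test_that("WTP thresholds are GDP multiples", {
  expect_equal(unname(wtp_thresholds(114e6)), c(114e6, 342e6))
  expect_equal(unname(wtp_thresholds(1, c(1, 3))), c(1, 3))
  expect_equal(unname(wtp_thresholds(50, c(1, 1))), c(50, 50))
})

test_that("quadrants, dominance and WTP bands follow the plane conventions", {
  gdp <- 114e6
  # NW: costlier, less effective -> dominated
  cl <- classify(89247958, -0.0718486, gdp)
  expect_equal(cl$quadrant, "NW")
  expect_equal(cl$dominance, "comparator_dominant")
  expect_equal(cl$wtp_band, "dominance_verdict")

  # SW in paper-compatible mode bands the raw ICER on the NE scale
  cl2 <- classify(-31280140, -0.1600799, gdp, mode = "paper_compatible")
  expect_equal(cl2$quadrant, "SW")
  expect_equal(cl2$dominance, "none")
  expect_equal(cl2$wtp_band, "cost_effective")  # 195.4M within [114M, 342M]

  # same point in quadrant-aware mode: savings of 195.4M per QALY forgone
  # exceed 1x GDP but not 3x GDP
  cl3 <- classify(-31280140, -0.1600799, gdp, mode = "quadrant_aware")
  expect_equal(cl3$wtp_band, "cost_effective")
  # enormous savings per QALY forgone become very cost-effective only in
  # quadrant-aware mode
  cl4 <- classify(-400e6, -1, gdp, mode = "quadrant_aware")
  expect_equal(cl4$wtp_band, "very_cost_effective")
  expect_equal(classify(-400e6, -1, gdp, mode = "paper_compatible")$wtp_band,
               "not_cost_effective")

  # SE: cheaper and more effective -> intervention dominant
  cl5 <- classify(-1, 1, gdp)
  expect_equal(cl5$quadrant, "SE")
  expect_equal(cl5$dominance, "intervention_dominant")

  # NE banding with closed boundaries
  expect_equal(classify(114e6, 1, gdp)$wtp_band, "very_cost_effective")
  expect_equal(classify(342e6, 1, gdp)$wtp_band, "cost_effective")
  expect_equal(classify(342e6 + 1, 1, gdp)$wtp_band, "not_cost_effective")
})

test_that("every sign combination, including zeros, maps to one defined verdict", {
  for (dc in c(-5, 0, 5)) {
    for (dq in c(-0.1, 0, 0.1)) {
      cl <- classify(dc, dq, 100)
      expect_true(cl$quadrant %in% c("NE", "NW", "SE", "SW"))
      expect_true(cl$dominance %in%
                    c("intervention_dominant", "comparator_dominant", "none"))
      expect_true(cl$wtp_band %in%
                    c("very_cost_effective", "cost_effective",
                      "not_cost_effective", "dominance_verdict"))
      expect_true(nzchar(cl$verdict))
      # dominance definition: weak inequality with at least one strict
      expect_equal(cl$dominance == "intervention_dominant",
                   dc <= 0 && dq >= 0 && (dc < 0 || dq > 0))
      expect_equal(cl$dominance == "comparator_dominant",
                   dc >= 0 && dq <= 0 && (dc > 0 || dq < 0))
    }
  }
  # zero QALY difference is cost-minimization, not an infinite ICER
  cl0 <- classify(5, 0, 100)
  expect_true(is.na(cl0$icer))
  expect_match(cl0$verdict, "cost-minimization")
})

test_that("fail-branch utility calibration solves the linear identity", {
  u <- calibrate_fail_utility(0.82070086, 0.8255, 0.777, 0.817)
  expect_equal(u, 0.70790, tolerance = 1e-4)

  # round trip through strategy_utility reproduces the reported total
  cfg <- vn
  cfg$u_fail <- u
  expect_equal(strategy_utility(cfg$strategies$atorvastatin, cfg)$total,
               0.82070086, tolerance = 1e-9)

  # total at the base weight forces u_fail = u_base
  p1 <- 0.6; p2 <- 0.7
  tot <- 0.88 * (p1 + (1 - p1) * p2) + (1 - p1) * (1 - p2) * 0.88
  expect_equal(calibrate_fail_utility(tot, 0.88, p1, p2), 0.88)

  expect_error(calibrate_fail_utility(0.8, 0.9, 1, 0.5), "zero probability")
})

test_that("calibration recovers the generating u_fail over random scenarios", {
  for (i in 1:1000) {
    cfg <- random_scenario(generator_spec(seed = i))
    s <- cfg$strategies[[1]]
    if ((1 - s$initial$p_attain) * (1 - s$escalated$p_attain) <= 1e-12) next
    tot <- strategy_utility(s, cfg)$total
    expect_equal(calibrate_fail_utility(tot, cfg$u_base,
                                        s$initial$p_attain, s$escalated$p_attain),
                 cfg$u_fail, tolerance = 1e-9)
  }
})

test_that("the two target-achieving branches recover the same u_fail", {
  # calibrating from pitavastatin and from rosuvastatin reported totals
  # yields the same fail-state utility to ~1e-4
  u_pit <- calibrate_scenario(vn, "pitavastatin", 0.81871072)
  u_ros <- calibrate_scenario(vn, "rosuvastatin", 0.81983168)
  expect_equal(u_pit, u_ros, tolerance = 1e-4)
})

test_that("complication-mixture composition of the fail utility behaves", {
  expect_equal(compose_fail_utility(0.8255, 0, 0.2), 0.8255)
  expect_equal(compose_fail_utility(0.8255, 0.4, 0.8255), 0.8255)
  # the complication utility consistent with the calibrated fail state
  u_fail <- calibrate_fail_utility(0.82070086, 0.8255, 0.777, 0.817)
  u_comp <- (u_fail - (1 - 0.145) * 0.8255) / 0.145
  expect_equal(compose_fail_utility(0.8255, 0.145, u_comp), u_fail)
  expect_equal(u_comp, 0.0149, tolerance = 5e-2)
})

test_that("threshold price: closed form, bisection and fixed point agree", {
  comp <- evaluate_strategy("atorvastatin", vn)
  cur <- compare_strategies(vn, "pitavastatin", "atorvastatin")

  # fixed point: targeting the current ICER returns the current price
  p_fix <- threshold_price(vn, "pitavastatin", "initial", comp, cur$icer)
  expect_equal(p_fix, 13500, tolerance = 1e-6)

  # closed form vs bisection to 1 currency unit, at a different target
  for (arm in c("initial", "escalated", "both")) {
    p_cf <- threshold_price(vn, "pitavastatin", arm, comp, 114e6)
    p_bi <- threshold_price(vn, "pitavastatin", arm, comp, 114e6,
                            method = "bisection")
    expect_lt(abs(p_cf - p_bi), 1)
    expect_gte(p_cf, 0)
  }

  # a target with no crossing in [0, 10x price] is reported, not fabricated
  expect_error(threshold_price(vn, "pitavastatin", "initial", comp, 1e15),
               "no threshold price in range")
})
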