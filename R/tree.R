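#' Path probabilities of the two-stage escalation tree
#'
#' With `p1` the attainment probability on the initial dose and `p2` on the
#' escalated dose, the three terminal branches have probabilities `p1`,
#' `(1 - p1) * p2` and `(1 - p1) * (1 - p2)`, which sum to one exactly.
#'
#' @param strategy A [strategy()].
#' @return Named numeric vector over `ACHIEVE_INITIAL`, `ACHIEVE_ESCALATED`,
#'   `FAIL`.
#' @export
branch_probabilities <- function(strategy) {
  p1 <- strategy$initial$p_attain
  p2 <- strategy$escalated$p_attain
  c(ACHIEVE_INITIAL = p1,
    ACHIEVE_ESCALATED = (1 - p1) * p2,
    FAIL = (1 - p1) * (1 - p2))
}

#' Overall probability of reaching the lipid target across both stages
#'
#' @param p1,p2 Attainment probabilities on the initial and escalated dose.
#' @return `p1 + (1 - p1) * p2`.
#' @export
overall_attainment <- function(p1, p2) {
  stopifnot(all(p1 >= 0 & p1 <= 1), all(p2 >= 0 & p2 <= 1))
  p1 + (1 - p1) * p2
}

horizon_days <- function(config) config$horizon_years * config$days_per_year

#' Drug plus monitoring cost of one terminal branch
#'
#' The no-escalation branch accrues the initial dose's daily price over the
#' full horizon plus `panels_if_no_escalation` lipid panels. Both escalation
#' branches (target reached on the doubled dose or never reached) accrue the
#' initial price up to `escalation_day`, the escalated price for the rest of
#' the horizon, and `panels_if_escalation` panels: patients who escalate stay
#' on the escalated dose either way, so their drug/monitoring costs are
#' identical and only downstream costs can differ between them.
#'
#' @param strategy A [strategy()].
#' @param branch One of `"ACHIEVE_INITIAL"`, `"ACHIEVE_ESCALATED"`, `"FAIL"`.
#' @param config A `cua_scenario`.
#' @return Cost in currency units, including any configured downstream cost
#'   for the branch.
#' @examples
#' cfg <- builtin_scenario()
#' branch_cost(cfg$strategies$pitavastatin, "ACHIEVE_INITIAL", cfg)  # 69,203,400
#' @export
branch_cost <- function(strategy, branch, config) {
  branch <- match.arg(branch, BRANCHES)
  H <- horizon_days(config)
  m <- config$monitoring
  drug_monitor <- if (branch == "ACHIEVE_INITIAL") {
    strategy$initial$daily_price * H +
      m$panels_if_no_escalation * m$tests_per_panel * m$test_unit_cost
  } else {
    strategy$initial$daily_price * config$escalation_day +
      strategy$escalated$daily_price * (H - config$escalation_day) +
      m$panels_if_escalation * m$tests_per_panel * m$test_unit_cost
  }
  drug_monitor + config$downstream_branch_costs[[branch]]
}

#' Total utility of a strategy and its per-branch contributions
#'
#' Each branch contributes its utility weight times its path probability:
#' `u_base` for either target-achieving branch, `u_fail` for the
#' never-controlled branch. The strategy total is the sum of the three
#' contributions, a convex combination lying between `u_fail` and `u_base`.
#'
#' @param strategy A [strategy()].
#' @param config A `cua_scenario`.
#' @return List with `total` (scalar) and `contributions` (named numeric over
#'   the three branches).
#' @export
strategy_utility <- function(strategy, config) {
  p <- branch_probabilities(strategy)
  w <- c(ACHIEVE_INITIAL = config$u_base,
         ACHIEVE_ESCALATED = config$u_base,
         FAIL = config$u_fail)
  contrib <- w * p
  list(total = sum(contrib), contributions = contrib)
}

## Effective year multiplier: plain horizon, or present value of an annual
## annuity at the configured rate.
lyg_multiplier <- function(config) {
  if (config$discount_mode == "none") {
    config$horizon_years
  } else {
    r <- config$discount_rate
    if (r == 0) config$horizon_years else (1 - (1 + r)^(-config$horizon_years)) / r
  }
}

#' Quality-adjusted life years from a utility weight
#'
#' `QALY = utility x LYG`, with the life-years-gained multiplier either the
#' raw horizon (`discount_mode = "none"`) or the present value of one
#' life-year per year discounted annually (`"annual_annuity"`).
#'
#' @param utility Utility weight in \[0, 1\].
#' @param config A `cua_scenario`.
#' @return QALYs.
#' @export
qaly <- function(utility, config) {
  stopifnot(all(utility >= 0 & utility <= 1))
  utility * lyg_multiplier(config)
}

#' Evaluate one strategy through the decision tree
#'
#' Computes the three branch probabilities, branch costs and utility
#' contributions, the overall attainment probability, the expected
#' (probability-weighted) total cost, the total utility and the QALY.
#'
#' @param strategy A [strategy()] or the name of a strategy in `config`.
#' @param config A `cua_scenario`.
#' @return A `cua_strategy_result`: list with `strategy_name`, `branches`
#'   (data frame: `branch`, `probability`, `cost`, `utility_contribution`),
#'   `overall_attainment`, `expected_cost`, `total_utility`, `qaly`, `lyg`.
#' @examples
#' cfg <- builtin_scenario()
#' evaluate_strategy("pitavastatin", cfg)
#' @export
evaluate_strategy <- function(strategy, config) {
  if (is.character(strategy)) {
    if (!strategy %in% names(config$strategies))
      stop("unknown strategy: ", strategy, call. = FALSE)
    strategy <- config$strategies[[strategy]]
  }
  p <- branch_probabilities(strategy)
  costs <- vapply(BRANCHES, function(b) branch_cost(strategy, b, config), numeric(1))
  u <- strategy_utility(strategy, config)
  res <- list(
    strategy_name = strategy$name,
    branches = data.frame(branch = BRANCHES,
                          probability = unname(p),
                          cost = unname(costs),
                          utility_contribution = unname(u$contributions)),
    overall_attainment = overall_attainment(strategy$initial$p_attain,
                                            strategy$escalated$p_attain),
    expected_cost = sum(p * costs),
    total_utility = u$total,
    qaly = qaly(u$total, config),
    lyg = config$horizon_years)
  class(res) <- "cua_strategy_result"
  res
}

#' Evaluate every strategy in a scenario
#'
#' @param config A `cua_scenario`.
#' @return Named list of `cua_strategy_result`, one per strategy.
#' @export
evaluate_scenario <- function(config) {
  lapply(config$strategies, evaluate_strategy, config = config)
}

#' Per-strategy summary table of an evaluated scenario
#'
#' @param results List of `cua_strategy_result` (from [evaluate_scenario()]).
#' @return Data frame with one row per strategy: expected cost, attainment,
#'   utility and QALY.
#' @export
strategy_table <- function(results) {
  do.call(rbind, lapply(unname(results), function(r) data.frame(
    strategy = r$strategy_name,
    cost_no_escalation = r$branches$cost[1],
    cost_escalation = r$branches$cost[2],
    expected_cost = r$expected_cost,
    overall_attainment = r$overall_attainment,
    total_utility = r$total_utility,
    qaly = r$qaly,
    lyg = r$lyg)))
}

#' @export
print.cua_strategy_result <- function(x, ...) {
  cat("<cua_strategy_result>", x$strategy_name, "\n")
  print(x$branches, row.names = FALSE)
  cat(sprintf("  overall attainment %.4f | expected cost %s | utility %.8f | QALY %.8f\n",
              x$overall_attainment, format_currency(x$expected_cost),
              x$total_utility, x$qaly))
  invisible(x)
}

## Currency display: integers as-is, fractional expected values to 1 decimal,
## rounding half away from zero.
format_currency <- function(x) {
  r <- round_half_away(x, 1)
  ifelse(r == trunc(r),
         formatC(r, format = "d", big.mark = ","),
         formatC(r, format = "f", digits = 1, big.mark = ","))
}

round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}
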