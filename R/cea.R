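## Incremental cost-utility analysis between two strategies: deltas, ICER,
## cost-effectiveness plane classification and WTP banding.

## Accept either a cua_strategy_result or a plain list/row with total cost and
## QALY (e.g. externally reported totals).
as_totals <- function(x) {
  if (inherits(x, "cua_strategy_result"))
    return(list(name = x$strategy_name, cost = x$expected_cost, qaly = x$qaly))
  nm <- x$name %||% x$strategy %||% NA_character_
  cost <- x$cost %||% x$total_cost %||% x$expected_cost
  q <- x$qaly %||% x$total_qaly
  if (is.null(cost) || is.null(q))
    stop("totals must carry a cost and a QALY", call. = FALSE)
  list(name = nm, cost = as.numeric(cost), qaly = as.numeric(q))
}

#' Incremental cost and QALY between intervention and comparator
#'
#' @param a Intervention: a `cua_strategy_result` or a list with
#'   `total_cost`/`cost` and `total_qaly`/`qaly`.
#' @param b Comparator, same forms.
#' @return List with `delta_cost` and `delta_qaly`, each `a - b`.
#' @export
incremental <- function(a, b) {
  ta <- as_totals(a); tb <- as_totals(b)
  list(delta_cost = ta$cost - tb$cost, delta_qaly = ta$qaly - tb$qaly)
}

#' Incremental cost-effectiveness ratio
#'
#' `delta_cost / delta_qaly`, sign preserved. A zero QALY difference has no
#' ICER; the comparison is then a cost-minimisation question, and this
#' function signals a classed error (`cua_undefined_icer`) rather than
#' dividing by zero. [classify()] handles that case directly.
#'
#' @param delta_cost,delta_qaly Incremental cost and QALYs.
#' @return Currency per QALY.
#' @export
icer <- function(delta_cost, delta_qaly) {
  if (delta_qaly == 0)
    stop(structure(
      list(message = "undefined ICER (delta QALY = 0); use cost-minimization",
           call = sys.call(-1)),
      class = c("cua_undefined_icer", "error", "condition")))
  delta_cost / delta_qaly
}

#' Willingness-to-pay cutpoints from GDP per capita
#'
#' WHO-convention bands: an ICER below one GDP per capita per QALY is very
#' cost-effective, within one to three times GDP cost-effective, above three
#' times GDP not cost-effective.
#'
#' @param gdp_per_capita GDP per capita (currency).
#' @param multipliers Length-2 multiples of GDP (default `c(1, 3)`).
#' @return Named numeric `c(lower, upper)`.
#' @export
wtp_thresholds <- function(gdp_per_capita, multipliers = c(1, 3)) {
  stopifnot(gdp_per_capita > 0, length(multipliers) == 2L)
  c(lower = gdp_per_capita * multipliers[1], upper = gdp_per_capita * multipliers[2])
}

sign3 <- function(x) if (x > 0) 1L else if (x < 0) -1L else 0L

#' Classify an incremental result on the cost-effectiveness plane
#'
#' Quadrants follow the (delta QALY, delta cost) sign convention: NE more
#' effective and costlier, NW less effective and costlier, SE more effective
#' and cheaper, SW less effective and cheaper. NW means the intervention is
#' dominated by the comparator; SE means it dominates. Axis cases are
#' resolved explicitly: a zero QALY difference is a cost-minimisation verdict
#' (the cheaper option weakly dominates), a zero cost difference with a QALY
#' difference is effectiveness-minimisation (the more effective option weakly
#' dominates), and two zeros are equivalence.
#'
#' Two banding modes are provided. `"paper_compatible"` (default) bands the
#' raw ICER against the lower/upper GDP cutpoints in both the NE and SW
#' quadrants — the convention used in the source analyses this package
#' reproduces, where a SW-quadrant ICER (savings per QALY forgone) is read
#' against the same scale as a NE-quadrant one. `"quadrant_aware"` applies
#' the standard decision-theoretic rule instead: in the SW quadrant larger
#' savings per QALY forgone are better, so the band ordering inverts
#' (acceptable iff the ICER is at least the threshold).
#'
#' Band boundaries are closed downwards: an ICER exactly at the lower
#' cutpoint is very cost-effective, exactly at the upper cutpoint is
#' cost-effective (mirrored in quadrant-aware SW).
#'
#' @param delta_cost,delta_qaly Incremental cost and QALYs (intervention
#'   minus comparator).
#' @param gdp_per_capita GDP per capita anchoring the thresholds.
#' @param multipliers GDP multiples, default `c(1, 3)`.
#' @param mode `"paper_compatible"` or `"quadrant_aware"`.
#' @return List with `quadrant` (`NE`/`NW`/`SE`/`SW`), `dominance`
#'   (`intervention_dominant`/`comparator_dominant`/`none`), `wtp_band`
#'   (`very_cost_effective`/`cost_effective`/`not_cost_effective`/
#'   `dominance_verdict`), `icer` (`NA` when undefined), and a human-readable
#'   `verdict`.
#' @export
classify <- function(delta_cost, delta_qaly, gdp_per_capita,
                     multipliers = c(1, 3),
                     mode = c("paper_compatible", "quadrant_aware")) {
  mode <- match.arg(mode)
  thr <- wtp_thresholds(gdp_per_capita, multipliers)
  sq <- sign3(delta_qaly); sc <- sign3(delta_cost)

  quadrant <- if (sq >= 0 && sc >= 0) "NE"
  else if (sq >= 0) "SE"
  else if (sc >= 0) "NW"
  else "SW"

  dominance <-
    if (sc <= 0 && sq >= 0 && (sc < 0 || sq > 0)) "intervention_dominant"
    else if (sc >= 0 && sq <= 0 && (sc > 0 || sq < 0)) "comparator_dominant"
    else "none"

  r <- if (sq != 0) delta_cost / delta_qaly else NA_real_

  band_ne <- function(r) {
    if (r <= thr[["lower"]]) "very_cost_effective"
    else if (r <= thr[["upper"]]) "cost_effective"
    else "not_cost_effective"
  }
  band_sw_inverted <- function(r) {
    if (r >= thr[["upper"]]) "very_cost_effective"
    else if (r >= thr[["lower"]]) "cost_effective"
    else "not_cost_effective"
  }

  if (sq == 0 && sc == 0) {
    wtp_band <- "dominance_verdict"
    verdict <- "equivalent: no cost or QALY difference"
  } else if (sq == 0) {
    wtp_band <- "dominance_verdict"
    verdict <- "cost-minimization: cheaper strategy preferred"
  } else if (dominance == "intervention_dominant") {
    wtp_band <- "dominance_verdict"
    verdict <- "intervention dominant (cheaper, at least as effective)"
  } else if (dominance == "comparator_dominant") {
    wtp_band <- "dominance_verdict"
    verdict <- "intervention dominated by comparator"
  } else {
    wtp_band <- if (quadrant == "NE" || mode == "paper_compatible") band_ne(r)
                else band_sw_inverted(r)
    verdict <- paste0(quadrant, " quadrant: ", gsub("_", " ", wtp_band))
  }

  list(quadrant = quadrant, dominance = dominance, wtp_band = wtp_band,
       icer = r, verdict = verdict, mode = mode, wtp_thresholds = thr)
}

#' Full pairwise comparison of two strategies
#'
#' Evaluates both strategies (or takes supplied totals), forms the
#' incremental cost and QALY, the ICER, and the cost-effectiveness plane
#' classification against the scenario's WTP thresholds.
#'
#' @param config A `cua_scenario`.
#' @param intervention,comparator Strategy names in `config`.
#' @param mode Banding mode, see [classify()].
#' @param totals_override Optional data frame with columns `strategy`,
#'   `total_cost`, `total_qaly` (e.g. [builtin_reference_totals()]): rows
#'   matching either strategy replace the tree-computed expected cost and
#'   QALY, letting the incremental layer run on externally reported totals.
#' @return A `cua_comparison` list: names, deltas, `icer`, `quadrant`,
#'   `dominance`, `wtp_band`, `verdict`, `mode`.
#' @examples
#' cfg <- builtin_scenario()
#' compare_strategies(cfg, "pitavastatin", "atorvastatin",
#'                    totals_override = builtin_reference_totals())
#' @export
compare_strategies <- function(config, intervention, comparator,
                               mode = c("paper_compatible", "quadrant_aware"),
                               totals_override = NULL) {
  mode <- match.arg(mode)
  get_tot <- function(nm) {
    if (!is.null(totals_override) && nm %in% totals_override$strategy) {
      row <- totals_override[totals_override$strategy == nm, , drop = FALSE]
      list(name = nm, cost = row$total_cost[1], qaly = row$total_qaly[1])
    } else {
      as_totals(evaluate_strategy(nm, config))
    }
  }
  ta <- get_tot(intervention); tb <- get_tot(comparator)
  inc <- incremental(list(cost = ta$cost, qaly = ta$qaly),
                     list(cost = tb$cost, qaly = tb$qaly))
  cl <- classify(inc$delta_cost, inc$delta_qaly, config$gdp_per_capita,
                 config$wtp_multipliers, mode)
  structure(
    list(intervention_name = intervention, comparator_name = comparator,
         intervention_cost = ta$cost, comparator_cost = tb$cost,
         intervention_qaly = ta$qaly, comparator_qaly = tb$qaly,
         delta_cost = inc$delta_cost, delta_qaly = inc$delta_qaly,
         icer = cl$icer, quadrant = cl$quadrant, dominance = cl$dominance,
         wtp_band = cl$wtp_band, verdict = cl$verdict, mode = mode),
    class = "cua_comparison")
}

#' @export
print.cua_comparison <- function(x, ...) {
  cat("<cua_comparison>", x$intervention_name, "vs", x$comparator_name,
      paste0("[", x$mode, "]"), "\n")
  cat(sprintf("  delta cost %s | delta QALY %.8f\n",
              format_currency(x$delta_cost), x$delta_qaly))
  if (is.na(x$icer)) cat("  ICER: undefined (delta QALY = 0)\n")
  else cat(sprintf("  ICER %s per QALY\n", format_currency(round_half_away(x$icer))))
  cat(sprintf("  %s / %s / %s\n  %s\n", x$quadrant, x$dominance, x$wtp_band, x$verdict))
  invisible(x)
}

#' Calibrate the fail-branch utility from a strategy's reported total
#'
#' The strategy total utility is linear in `u_fail`:
#' `total = u_base * (p1 + (1 - p1) * p2) + (1 - p1) * (1 - p2) * u_fail`,
#' so a single reported total identifies `u_fail` in closed form provided
#' the fail branch has positive probability.
#'
#' @param printed_total_utility Reported total utility of the strategy.
#' @param u_base Utility weight of target-achievers.
#' @param p1,p2 Attainment probabilities of the initial and escalated dose.
#' @return The implied `u_fail`.
#' @examples
#' calibrate_fail_utility(0.82070086, 0.8255, 0.777, 0.817)  # ~0.7079
#' @export
calibrate_fail_utility <- function(printed_total_utility, u_base, p1, p2) {
  p_fail <- (1 - p1) * (1 - p2)
  if (p_fail <= 0)
    stop("fail branch has zero probability; u_fail is unidentifiable",
         call. = FALSE)
  p_ach <- p1 + (1 - p1) * p2
  (printed_total_utility - u_base * p_ach) / p_fail
}

#' Compose a fail-state utility from a complication probability
#'
#' Mixture form: with probability `p_complication` the uncontrolled patient
#' carries the complication utility, otherwise the base utility:
#' `(1 - p_complication) * u_base + p_complication * u_complication`.
#'
#' @param u_base Base utility weight.
#' @param p_complication Complication probability in \[0, 1\].
#' @param u_complication Utility weight of the complicated state.
#' @return The composed fail-state utility.
#' @export
compose_fail_utility <- function(u_base, p_complication, u_complication) {
  stopifnot(p_complication >= 0, p_complication <= 1)
  (1 - p_complication) * u_base + p_complication * u_complication
}

## Expected cost of a strategy as an affine function of one (or both) of its
## daily prices: returns intercept a and slope b with E[cost] = a + b * price
## (price applied to the selected arm(s); with arm = "both" the two arms are
## locked to a single common price).
cost_affine_in_price <- function(config, strategy_name, arm) {
  set_price <- function(p) {
    s <- config$strategies[[strategy_name]]
    if (arm %in% c("initial", "both")) s$initial$daily_price <- p
    if (arm %in% c("escalated", "both")) s$escalated$daily_price <- p
    evaluate_strategy(s, config)$expected_cost
  }
  a <- set_price(0)
  b <- set_price(1) - a
  list(a = a, b = b)
}

#' Daily price at which a comparison's ICER crosses a target threshold
#'
#' Expected cost is affine in each daily price, and prices do not affect
#' QALYs, so the price at which `ICER = target_wtp` has a closed form:
#' solve `a + b * price - comparator_cost = target_wtp * delta_qaly` for
#' `price`. Prices are bounded below by zero and the search range above by
#' ten times the current price; a crossing outside that range is reported as
#' an error. A bisection solver over the same range is available as a
#' cross-check and agrees with the closed form to 1 currency unit.
#'
#' @param config A `cua_scenario`.
#' @param strategy_name Strategy whose price is varied.
#' @param arm `"initial"`, `"escalated"`, or `"both"` (both arms locked to
#'   one common price).
#' @param comparator Comparator totals: a strategy name in `config`, a
#'   `cua_strategy_result`, or a list with cost and QALY.
#' @param target_wtp Target ICER (currency per QALY).
#' @param method `"closed_form"` (default) or `"bisection"`.
#' @return The threshold daily price (currency, >= 0).
#' @export
threshold_price <- function(config, strategy_name,
                            arm = c("initial", "escalated", "both"),
                            comparator, target_wtp,
                            method = c("closed_form", "bisection")) {
  arm <- match.arg(arm)
  method <- match.arg(method)
  if (!strategy_name %in% names(config$strategies))
    stop("unknown strategy: ", strategy_name, call. = FALSE)
  comp <- if (is.character(comparator)) {
    as_totals(evaluate_strategy(comparator, config))
  } else as_totals(comparator)

  s <- config$strategies[[strategy_name]]
  cur_price <- switch(arm, initial = s$initial$daily_price,
                      escalated = s$escalated$daily_price,
                      both = max(s$initial$daily_price, s$escalated$daily_price))
  upper <- 10 * cur_price
  dq <- qaly(strategy_utility(s, config)$total, config) - comp$qaly
  if (dq == 0)
    stop("delta QALY is zero; the ICER is undefined at every price", call. = FALSE)

  af <- cost_affine_in_price(config, strategy_name, arm)
  if (af$b == 0)
    stop("expected cost does not depend on the ", arm, " price here; no threshold",
         call. = FALSE)

  if (method == "closed_form") {
    price <- (target_wtp * dq + comp$cost - af$a) / af$b
  } else {
    f <- function(p) (af$a + af$b * p - comp$cost) / dq - target_wtp
    lo <- 0; hi <- upper
    if (f(lo) * f(hi) > 0)
      stop("no threshold price in range [0, ", upper, "]", call. = FALSE)
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      if (f(lo) * f(mid) <= 0) hi <- mid else lo <- mid
      if (hi - lo < 1e-9) break
    }
    price <- (lo + hi) / 2
  }
  if (price < 0 || price > upper)
    stop("no threshold price in range [0, ", upper, "]", call. = FALSE)
  price
}
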