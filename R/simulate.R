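## Seeded generator of synthetic scenarios with the structural shape the
## analysis assumes: two-arm dose-escalation strategies, probabilities in
## (0, 1), positive prices, base utility above fail utility.

#' Specification for the random scenario generator
#'
#' Ranges default to a factor of 0.5 to 2 around the packaged Vietnam 2024
#' values so synthetic scenarios stay in a realistic regime for daily statin
#' prices (VND), attainment probabilities, utilities and horizon. Setting
#' `strategy_ranges` (a per-strategy list of point or interval values, as
#' produced by [generator_spec_from_scenario()]) pins individual strategies
#' instead of drawing them from the global ranges.
#'
#' @param seed Integer seed; the single source of randomness.
#' @param n_strategies Number of strategies to generate.
#' @param price_range Interval for daily prices (VND/day).
#' @param p1_range,p2_range Intervals for initial/escalated attainment
#'   probabilities.
#' @param p2_ge_p1 If `TRUE` (default), the escalated dose is drawn at least
#'   as effective as the initial dose.
#' @param u_base_range Interval for the base utility weight.
#' @param u_gap_range Interval for `u_base - u_fail`.
#' @param horizon_range Interval for the horizon in whole years.
#' @param dose_monotone_pricing If `TRUE` (default), the escalated arm's
#'   price is drawn at least as high as the initial arm's.
#' @param strategy_ranges Optional list: per strategy, a list with elements
#'   `name`, `initial_price`, `escalated_price`, `p1`, `p2`, each value a
#'   point or `c(lo, hi)` interval. Overrides `n_strategies` and the global
#'   strategy ranges.
#' @return A `cua_generator_spec` object.
#' @export
generator_spec <- function(seed = 1L, n_strategies = 3,
                           price_range = c(4489, 37000),
                           p1_range = c(0.36, 0.95), p2_range = c(0.40, 0.98),
                           p2_ge_p1 = TRUE,
                           u_base_range = c(0.41, 1),
                           u_gap_range = c(0, 0.235),
                           horizon_range = c(7, 28),
                           dose_monotone_pricing = TRUE,
                           strategy_ranges = NULL) {
  spec <- structure(
    list(seed = as.integer(seed), n_strategies = as.integer(n_strategies),
         price_range = as.numeric(price_range),
         p1_range = as.numeric(p1_range), p2_range = as.numeric(p2_range),
         p2_ge_p1 = isTRUE(p2_ge_p1),
         u_base_range = as.numeric(u_base_range),
         u_gap_range = as.numeric(u_gap_range),
         horizon_range = as.numeric(horizon_range),
         dose_monotone_pricing = isTRUE(dose_monotone_pricing),
         strategy_ranges = strategy_ranges),
    class = "cua_generator_spec")
  for (f in c("price_range", "p1_range", "p2_range", "u_base_range",
              "u_gap_range", "horizon_range")) {
    r <- spec[[f]]
    if (length(r) != 2L || any(!is.finite(r)) || r[1] > r[2])
      stop(f, " must be a non-empty interval c(lo, hi)", call. = FALSE)
  }
  stopifnot(spec$price_range[1] >= 0,
            spec$p1_range[1] >= 0, spec$p1_range[2] <= 1,
            spec$p2_range[1] >= 0, spec$p2_range[2] <= 1,
            spec$u_base_range[1] >= 0, spec$u_base_range[2] <= 1,
            spec$u_gap_range[1] >= 0, spec$horizon_range[1] > 0)
  spec
}

#' Generator spec whose intervals collapse onto an existing scenario
#'
#' Every range becomes a point mass at the scenario's value, so
#' [random_scenario()] reproduces the scenario exactly (useful for checking
#' the generator against the packaged fixture).
#'
#' @param config A `cua_scenario`.
#' @param seed Seed carried into the spec.
#' @return A `cua_generator_spec`.
#' @export
generator_spec_from_scenario <- function(config, seed = 1L) {
  pt <- function(x) c(x, x)
  spec <- generator_spec(
    seed = seed,
    n_strategies = length(config$strategies),
    u_base_range = pt(config$u_base),
    u_gap_range = pt(config$u_base - config$u_fail),
    horizon_range = pt(config$horizon_years),
    strategy_ranges = lapply(unname(config$strategies), function(s) list(
      name = s$name,
      initial_price = pt(s$initial$daily_price),
      escalated_price = pt(s$escalated$daily_price),
      p1 = pt(s$initial$p_attain),
      p2 = pt(s$escalated$p_attain),
      initial_label = s$initial$label,
      escalated_label = s$escalated$label)))
  spec$template <- config
  spec
}

runif1 <- function(r) stats::runif(1, r[1], r[2])

#' Draw one random, valid scenario
#'
#' Deterministic given `spec$seed` (the seed is applied locally and global
#' random state is left untouched). Every draw passes
#' [validate_scenario()] by construction. When the spec carries a template
#' scenario (see [generator_spec_from_scenario()]) the non-strategy fields
#' (monitoring, discounting, WTP settings) are copied from it; otherwise
#' fixture-like defaults are used.
#'
#' @param spec A [generator_spec()].
#' @return A validated `cua_scenario`.
#' @export
random_scenario <- function(spec) {
  stopifnot(inherits(spec, "cua_generator_spec"))
  withr::with_seed(spec$seed, {
    strat_specs <- spec$strategy_ranges
    if (is.null(strat_specs)) {
      strat_specs <- lapply(seq_len(spec$n_strategies), function(i) list(
        name = paste0("strategy_", LETTERS[((i - 1L) %% 26L) + 1L], i),
        initial_price = spec$price_range, escalated_price = spec$price_range,
        p1 = spec$p1_range, p2 = spec$p2_range))
    }
    strategies <- lapply(strat_specs, function(ss) {
      price_i <- runif1(ss$initial_price)
      price_e <- runif1(ss$escalated_price)
      if (spec$dose_monotone_pricing && price_e < price_i &&
          is.null(spec$strategy_ranges)) {
        price_e <- stats::runif(1, price_i, spec$price_range[2])
      }
      p1 <- runif1(ss$p1)
      p2 <- runif1(ss$p2)
      if (spec$p2_ge_p1 && p2 < p1 && is.null(spec$strategy_ranges)) {
        p2 <- stats::runif(1, p1, spec$p2_range[2])
      }
      strategy(ss$name,
               dose_arm(ss$initial_label %||% paste(ss$name, "initial dose"),
                        round(price_i), p1),
               dose_arm(ss$escalated_label %||% paste(ss$name, "escalated dose"),
                        round(price_e), p2))
    })
    u_base <- runif1(spec$u_base_range)
    u_fail <- max(0, u_base - runif1(spec$u_gap_range))
    horizon <- round(runif1(spec$horizon_range))
    tmpl <- spec$template
    dpy <- tmpl$days_per_year %||% 365
    scenario_config(
      strategies = strategies,
      monitoring = tmpl$monitoring %||% monitoring_plan(test_unit_cost = 27300),
      horizon_years = horizon,
      days_per_year = dpy,
      escalation_day = if (is.null(tmpl)) min(56, horizon * dpy - 1) else tmpl$escalation_day,
      u_base = u_base, u_fail = u_fail,
      p_complication = tmpl$p_complication,
      discount_rate = tmpl$discount_rate %||% 0.03,
      discount_mode = tmpl$discount_mode %||% "none",
      gdp_per_capita = tmpl$gdp_per_capita %||% 114000000,
      wtp_multipliers = tmpl$wtp_multipliers %||% c(1, 3),
      usd_exchange_rate = tmpl$usd_exchange_rate,
      name = tmpl$name %||% paste0("synthetic_seed_", spec$seed))
  })
}

#' Multiplicative jitter around an existing scenario
#'
#' Each numeric model parameter is multiplied by an independent lognormal
#' factor with log-scale standard deviation `relative_sd` (so
#' `relative_sd = 0` returns the base scenario unchanged). Probabilities and
#' utilities are clamped back to \[0, 1\] and `u_fail` is capped at `u_base`,
#' so the result always validates. Deterministic given `seed`; global random
#' state is untouched.
#'
#' @param base A `cua_scenario`.
#' @param seed Integer seed.
#' @param relative_sd Relative spread of the jitter factors (fraction).
#' @return A validated `cua_scenario`.
#' @export
jitter_scenario <- function(base, seed = 1L, relative_sd = 0.1) {
  stopifnot(relative_sd >= 0)
  withr::with_seed(as.integer(seed), {
    jit <- function(x) x * exp(stats::rnorm(1, 0, relative_sd))
    clamp01 <- function(x) min(max(x, 0), 1)
    out <- base
    for (nm in names(out$strategies)) {
      for (side in c("initial", "escalated")) {
        out$strategies[[nm]][[side]]$daily_price <-
          jit(out$strategies[[nm]][[side]]$daily_price)
        out$strategies[[nm]][[side]]$p_attain <-
          clamp01(jit(out$strategies[[nm]][[side]]$p_attain))
      }
    }
    for (f in c("tests_per_panel", "test_unit_cost",
                "panels_if_no_escalation", "panels_if_escalation"))
      out$monitoring[[f]] <- jit(out$monitoring[[f]])
    out$u_base <- clamp01(jit(out$u_base))
    out$u_fail <- min(clamp01(jit(out$u_fail)), out$u_base)
    if (!is.null(out$p_complication))
      out$p_complication <- clamp01(jit(out$p_complication))
    out$downstream_branch_costs[] <- vapply(out$downstream_branch_costs, jit,
                                            numeric(1))
    v <- validate_scenario(out)
    if (nrow(v) > 0)
      stop("jitter produced an invalid scenario (internal error):\n",
           paste0("  ", v$field, ": ", v$rule, collapse = "\n"), call. = FALSE)
    out
  })
}
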