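#' @keywords internal
#' @importFrom rlang .data
"_PACKAGE"

## Branch labels of the two-stage escalation tree, in evaluation order.
BRANCHES <- c("ACHIEVE_INITIAL", "ACHIEVE_ESCALATED", "FAIL")

#' One dose of one drug: daily acquisition price and target-attainment
#' probability
#'
#' @param label Free-text description, e.g. `"pitavastatin 2 mg"`.
#' @param daily_price Daily acquisition cost in currency units (VND); must be
#'   non-negative.
#' @param p_attain Probability of reaching the LDL-C target on this dose, in
#'   \[0, 1\].
#' @return A `cua_dose_arm` object.
#' @export
dose_arm <- function(label = "", daily_price, p_attain) {
  structure(
    list(label = as.character(label),
         daily_price = as.numeric(daily_price),
         p_attain = as.numeric(p_attain)),
    class = "cua_dose_arm"
  )
}

#' A two-stage treatment strategy: initial dose, escalated dose on failure
#'
#' Patients start on `initial`; those missing the lipid target at the
#' reassessment visit are switched to `escalated` (typically double the
#' initial dose) for the remainder of the horizon. The escalated arm may
#' share the initial arm's price (the atorvastatin case in the packaged
#' scenario).
#'
#' @param name Strategy name, unique within a scenario.
#' @param initial,escalated [dose_arm()] objects.
#' @return A `cua_strategy` object.
#' @export
strategy <- function(name, initial, escalated) {
  stopifnot(inherits(initial, "cua_dose_arm"), inherits(escalated, "cua_dose_arm"))
  structure(list(name = as.character(name), initial = initial, escalated = escalated),
            class = "cua_strategy")
}

#' Lipid-panel monitoring schedule and unit test cost
#'
#' @param tests_per_panel Number of laboratory tests per lipid panel
#'   (default 4: total cholesterol, HDL-C, LDL-C, triglycerides).
#' @param test_unit_cost Cost of one laboratory test (VND).
#' @param panels_if_no_escalation Panels billed on the no-escalation path
#'   (default 2: baseline and the reassessment visit).
#' @param panels_if_escalation Panels billed when the dose is escalated
#'   (default 3: one extra panel after the escalated interval).
#' @return A `cua_monitoring` object.
#' @export
monitoring_plan <- function(tests_per_panel = 4, test_unit_cost,
                            panels_if_no_escalation = 2, panels_if_escalation = 3) {
  structure(
    list(tests_per_panel = as.numeric(tests_per_panel),
         test_unit_cost = as.numeric(test_unit_cost),
         panels_if_no_escalation = as.numeric(panels_if_no_escalation),
         panels_if_escalation = as.numeric(panels_if_escalation)),
    class = "cua_monitoring"
  )
}

#' Full parameterisation of a dose-escalation cost-utility scenario
#'
#' Bundles the treatment strategies, monitoring schedule, horizon,
#' utilities, discounting and willingness-to-pay settings consumed by
#' [evaluate_strategy()], [compare_strategies()] and [one_way()].
#'
#' @param strategies List of [strategy()] objects with unique names.
#' @param monitoring A [monitoring_plan()].
#' @param horizon_years Model horizon in years (life-years gained; default 14).
#' @param days_per_year Days per model year (default 365).
#' @param escalation_day Day index at which failures switch dose (default 56,
#'   i.e. 8 weeks); must fall inside the horizon.
#' @param u_base Utility weight of patients at the lipid target, in \[0, 1\].
#' @param u_fail Utility weight of the never-controlled branch;
#'   `0 <= u_fail <= u_base`.
#' @param p_complication Probability of a major cardiovascular complication in
#'   the uncontrolled state; stored for [compose_fail_utility()], not used by
#'   the tree itself. `NULL` to omit.
#' @param discount_rate Annual discount rate as a fraction (default 0.03).
#' @param discount_mode `"none"` (utility times horizon, the reproduction
#'   default) or `"annual_annuity"` (utility times the present value of an
#'   annual annuity at `discount_rate`). See the package vignette for why
#'   `"none"` is the default.
#' @param gdp_per_capita GDP per capita (VND), the willingness-to-pay anchor.
#' @param wtp_multipliers Length-2 vector of GDP multiples bounding the
#'   "very cost-effective" and "cost-effective" bands (default `c(1, 3)`).
#' @param downstream_branch_costs Named numeric of per-branch lifetime
#'   downstream costs (names among `ACHIEVE_INITIAL`, `ACHIEVE_ESCALATED`,
#'   `FAIL`); defaults to zero. Stand-in for cost components outside the
#'   drug/monitoring inputs.
#' @param usd_exchange_rate Optional display-only VND/USD rate; never used in
#'   model arithmetic.
#' @param name Optional scenario identifier.
#' @return A validated `cua_scenario` object.
#' @seealso [load_scenario()], [builtin_scenario()], [validate_scenario()]
#' @export
scenario_config <- function(strategies, monitoring,
                            horizon_years = 14, days_per_year = 365,
                            escalation_day = 56,
                            u_base, u_fail, p_complication = NULL,
                            discount_rate = 0.03,
                            discount_mode = c("none", "annual_annuity"),
                            gdp_per_capita, wtp_multipliers = c(1, 3),
                            downstream_branch_costs = NULL,
                            usd_exchange_rate = NULL, name = NULL) {
  discount_mode <- match.arg(discount_mode)
  if (inherits(strategies, "cua_strategy")) strategies <- list(strategies)
  names(strategies) <- vapply(strategies, function(s) s$name, character(1))
  dbc <- stats::setNames(numeric(3), BRANCHES)
  if (!is.null(downstream_branch_costs)) {
    bad <- setdiff(names(downstream_branch_costs), BRANCHES)
    if (length(bad))
      stop("downstream_branch_costs: unknown branch name(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    dbc[names(downstream_branch_costs)] <- as.numeric(downstream_branch_costs)
  }
  cfg <- structure(
    list(name = name,
         strategies = strategies,
         monitoring = monitoring,
         horizon_years = as.numeric(horizon_years),
         days_per_year = as.numeric(days_per_year),
         escalation_day = as.numeric(escalation_day),
         u_base = as.numeric(u_base),
         u_fail = as.numeric(u_fail),
         p_complication = if (is.null(p_complication)) NULL else as.numeric(p_complication),
         discount_rate = as.numeric(discount_rate),
         discount_mode = discount_mode,
         gdp_per_capita = as.numeric(gdp_per_capita),
         wtp_multipliers = as.numeric(wtp_multipliers),
         downstream_branch_costs = dbc,
         usd_exchange_rate = if (is.null(usd_exchange_rate)) NULL else as.numeric(usd_exchange_rate)),
    class = "cua_scenario"
  )
  v <- validate_scenario(cfg)
  if (nrow(v) > 0)
    stop("invalid scenario:\n", paste0("  ", v$field, ": ", v$rule, collapse = "\n"),
         call. = FALSE)
  cfg
}

#' Check every scenario invariant, returning violations as data
#'
#' Unlike [scenario_config()] and [load_scenario()], which raise an error,
#' this returns violations as a data frame so callers can inspect them; an
#' empty frame means the scenario is valid.
#'
#' @param config A `cua_scenario` (or a structurally similar list).
#' @return Data frame with columns `field` and `rule`; zero rows iff valid.
#' @export
validate_scenario <- function(config) {
  bad <- list()
  note <- function(field, rule) bad[[length(bad) + 1L]] <<- data.frame(field = field, rule = rule)
  num_ok <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

  if (!length(config$strategies)) note("strategies", "at least one strategy required")
  nms <- names(config$strategies)
  if (anyDuplicated(nms)) note("strategies", "strategy names must be unique")
  for (s in config$strategies) {
    for (side in c("initial", "escalated")) {
      arm <- s[[side]]
      f <- paste0("strategies.", s$name, ".", side)
      if (is.null(arm)) { note(f, "dose arm missing"); next }
      if (!num_ok(arm$daily_price) || arm$daily_price < 0)
        note(paste0(f, ".daily_price"), "must be a non-negative number")
      if (!num_ok(arm$p_attain) || arm$p_attain < 0 || arm$p_attain > 1)
        note(paste0(f, ".p_attain"), "must be a probability in [0, 1]")
    }
  }
  m <- config$monitoring
  for (fld in c("tests_per_panel", "test_unit_cost",
                "panels_if_no_escalation", "panels_if_escalation")) {
    if (!num_ok(m[[fld]]) || m[[fld]] < 0)
      note(paste0("monitoring.", fld), "must be a non-negative number")
  }
  if (!num_ok(config$horizon_years) || config$horizon_years <= 0)
    note("horizon_years", "must be > 0")
  if (!num_ok(config$days_per_year) || config$days_per_year <= 0)
    note("days_per_year", "must be > 0")
  if (num_ok(config$horizon_years) && num_ok(config$days_per_year) &&
      (!num_ok(config$escalation_day) || config$escalation_day < 0 ||
       config$escalation_day >= config$horizon_years * config$days_per_year))
    note("escalation_day", "must satisfy 0 <= escalation_day < horizon_years * days_per_year")
  if (!num_ok(config$u_base) || config$u_base < 0 || config$u_base > 1)
    note("u_base", "must be in [0, 1]")
  if (!num_ok(config$u_fail) || config$u_fail < 0 || config$u_fail > 1)
    note("u_fail", "must be in [0, 1]")
  if (num_ok(config$u_base) && num_ok(config$u_fail) && config$u_fail > config$u_base)
    note("u_fail", "must satisfy u_fail <= u_base")
  if (!is.null(config$p_complication) &&
      (!num_ok(config$p_complication) || config$p_complication < 0 || config$p_complication > 1))
    note("p_complication", "must be a probability in [0, 1]")
  if (!num_ok(config$discount_rate) || config$discount_rate < 0)
    note("discount_rate", "must be >= 0")
  if (!is.character(config$discount_mode) ||
      !config$discount_mode %in% c("none", "annual_annuity"))
    note("discount_mode", "must be 'none' or 'annual_annuity'")
  if (!num_ok(config$gdp_per_capita) || config$gdp_per_capita <= 0)
    note("gdp_per_capita", "must be > 0")
  w <- config$wtp_multipliers
  if (!is.numeric(w) || length(w) != 2L || any(!is.finite(w)) || w[1] <= 0 || w[1] > w[2])
    note("wtp_multipliers", "must be two numbers with 0 < first <= second")
  d <- config$downstream_branch_costs
  if (!is.numeric(d) || !setequal(names(d), BRANCHES) || any(!is.finite(d)) || any(d < 0))
    note("downstream_branch_costs", "must be non-negative costs named by branch")
  if (!is.null(config$usd_exchange_rate) &&
      (!num_ok(config$usd_exchange_rate) || config$usd_exchange_rate <= 0))
    note("usd_exchange_rate", "must be > 0")

  if (length(bad)) do.call(rbind, bad) else data.frame(field = character(), rule = character())
}

## --- document parsing ------------------------------------------------------

# Reject keys not in `allowed`, reporting the dotted path.
assert_known_keys <- function(x, allowed, path) {
  extra <- setdiff(names(x), allowed)
  if (length(extra))
    stop("unknown key(s) at ", path, ": ", paste(extra, collapse = ", "), call. = FALSE)
}

need <- function(x, key, path) {
  if (is.null(x[[key]]))
    stop("missing required field ", path, ".", key, call. = FALSE)
  x[[key]]
}

parse_dose_arm <- function(x, path) {
  assert_known_keys(x, c("label", "daily_price", "p_attain"), path)
  dose_arm(label = x$label %||% "",
           daily_price = need(x, "daily_price", path),
           p_attain = need(x, "p_attain", path))
}

parse_strategy <- function(x, path) {
  assert_known_keys(x, c("name", "initial", "escalated"), path)
  nm <- need(x, "name", path)
  strategy(nm,
           initial = parse_dose_arm(need(x, "initial", path), paste0(path, ".initial")),
           escalated = parse_dose_arm(need(x, "escalated", path), paste0(path, ".escalated")))
}

#' Load and validate a scenario document (YAML or JSON)
#'
#' YAML is accepted as a superset of JSON, so either dialect parses. Optional
#' fields take their documented defaults; unknown keys are errors, so a
#' misspelled parameter can never be silently ignored. The schema is shipped
#' at `system.file("extdata", "scenario_schema.yaml", package = "cuatree")`.
#'
#' @param document Path to a file, or a single string holding the document
#'   text itself.
#' @return A validated `cua_scenario`.
#' @examples
#' cfg <- load_scenario(system.file("extdata", "vietnam_dyslipidemia_2024.yaml",
#'                                  package = "cuatree"))
#' cfg$strategies$rosuvastatin$initial$daily_price
#' @export
load_scenario <- function(document) {
  raw <- if (length(document) == 1L && !grepl("\n", document) && file.exists(document)) {
    yaml::read_yaml(document)
  } else {
    yaml::yaml.load(paste(document, collapse = "\n"))
  }
  if (!is.list(raw)) stop("scenario document did not parse to a mapping", call. = FALSE)
  assert_known_keys(raw, c("name", "strategies", "monitoring", "horizon_years",
                           "days_per_year", "escalation_day", "u_base", "u_fail",
                           "p_complication", "discount_rate", "discount_mode",
                           "gdp_per_capita", "wtp_multipliers",
                           "downstream_branch_costs", "usd_exchange_rate"),
                    "(root)")
  strategies <- lapply(seq_along(need(raw, "strategies", "(root)")), function(i)
    parse_strategy(raw$strategies[[i]], paste0("strategies[", i, "]")))
  mraw <- need(raw, "monitoring", "(root)")
  assert_known_keys(mraw, c("tests_per_panel", "test_unit_cost",
                            "panels_if_no_escalation", "panels_if_escalation"),
                    "monitoring")
  monitoring <- monitoring_plan(
    tests_per_panel = mraw$tests_per_panel %||% 4,
    test_unit_cost = need(mraw, "test_unit_cost", "monitoring"),
    panels_if_no_escalation = mraw$panels_if_no_escalation %||% 2,
    panels_if_escalation = mraw$panels_if_escalation %||% 3)
  dbc <- raw$downstream_branch_costs
  if (!is.null(dbc)) {
    assert_known_keys(dbc, BRANCHES, "downstream_branch_costs")
    dbc <- unlist(dbc)
  }
  scenario_config(
    strategies = strategies, monitoring = monitoring,
    horizon_years = raw$horizon_years %||% 14,
    days_per_year = raw$days_per_year %||% 365,
    escalation_day = raw$escalation_day %||% 56,
    u_base = need(raw, "u_base", "(root)"),
    u_fail = need(raw, "u_fail", "(root)"),
    p_complication = raw$p_complication,
    discount_rate = raw$discount_rate %||% 0.03,
    discount_mode = raw$discount_mode %||% "none",
    gdp_per_capita = need(raw, "gdp_per_capita", "(root)"),
    wtp_multipliers = unlist(raw$wtp_multipliers %||% c(1, 3)),
    downstream_branch_costs = dbc,
    usd_exchange_rate = raw$usd_exchange_rate,
    name = raw$name)
}

#' Serialise a scenario back to a YAML document
#'
#' Round-trips with [load_scenario()]: writing and re-loading yields an
#' equivalent configuration.
#'
#' @param config A `cua_scenario`.
#' @param path Output file; if `NULL`, the YAML text is returned invisibly.
#' @return The YAML text, invisibly.
#' @export
write_scenario <- function(config, path = NULL) {
  as_plain <- list(
    name = config$name,
    strategies = lapply(unname(config$strategies), function(s) list(
      name = s$name,
      initial = list(label = s$initial$label,
                     daily_price = s$initial$daily_price,
                     p_attain = s$initial$p_attain),
      escalated = list(label = s$escalated$label,
                       daily_price = s$escalated$daily_price,
                       p_attain = s$escalated$p_attain))),
    monitoring = unclass(config$monitoring),
    horizon_years = config$horizon_years,
    days_per_year = config$days_per_year,
    escalation_day = config$escalation_day,
    u_base = config$u_base,
    u_fail = config$u_fail,
    p_complication = config$p_complication,
    discount_rate = config$discount_rate,
    discount_mode = config$discount_mode,
    gdp_per_capita = config$gdp_per_capita,
    wtp_multipliers = config$wtp_multipliers,
    downstream_branch_costs = as.list(config$downstream_branch_costs),
    usd_exchange_rate = config$usd_exchange_rate)
  as_plain <- Filter(Negate(is.null), as_plain)
  txt <- yaml::as.yaml(as_plain, precision = 15)
  if (!is.null(path)) writeLines(txt, path)
  invisible(txt)
}

#' Packaged scenarios
#'
#' `"vietnam_dyslipidemia_2024"` is the Vietnam 2024 statin dose-escalation
#' scenario: pitavastatin 2/4 mg, atorvastatin 10/20 mg and rosuvastatin
#' 5/10 mg compared over a 14-year horizon at 2024 Vietnamese drug-tender
#' prices and laboratory fees, with GDP per capita VND 114,000,000 anchoring
#' the willingness-to-pay bands.
#'
#' @param name Fixture identifier.
#' @return A validated `cua_scenario`.
#' @export
builtin_scenario <- function(name = "vietnam_dyslipidemia_2024") {
  path <- system.file("extdata", paste0(name, ".yaml"), package = "cuatree")
  if (path == "" || !file.exists(path))
    stop("unknown builtin scenario: ", name, call. = FALSE)
  load_scenario(path)
}

#' Reported per-strategy totals accompanying a packaged scenario
#'
#' The Vietnam 2024 scenario ships with the externally reported strategy
#' totals (total utility, total QALY and total lifetime cost). Total cost and
#' total QALY include downstream components beyond the drug/monitoring inputs
#' and are therefore useful as a totals override in [compare_strategies()];
#' total utility is fully determined by the tree inputs and serves as a
#' calibration anchor for [calibrate_fail_utility()].
#'
#' @param name Fixture identifier.
#' @return Data frame with columns `strategy`, `total_utility`, `total_qaly`,
#'   `total_cost`.
#' @export
builtin_reference_totals <- function(name = "vietnam_dyslipidemia_2024") {
  path <- system.file("extdata", paste0(name, "_reference_totals.yaml"),
                      package = "cuatree")
  ## fixture file is named vietnam_reference_totals.yaml for the packaged case
  if (path == "" || !file.exists(path))
    path <- system.file("extdata", "vietnam_reference_totals.yaml", package = "cuatree")
  raw <- yaml::read_yaml(path)
  if (!identical(raw$name, name))
    stop("no reference totals for scenario: ", name, call. = FALSE)
  do.call(rbind, lapply(names(raw$strategies), function(nm) {
    s <- raw$strategies[[nm]]
    data.frame(strategy = nm, total_utility = s$total_utility,
               total_qaly = s$total_qaly, total_cost = s$total_cost)
  }))
}

#' @export
print.cua_scenario <- function(x, ...) {
  cat("<cua_scenario>", if (!is.null(x$name)) x$name else "", "\n")
  cat("  strategies:", paste(names(x$strategies), collapse = ", "), "\n")
  cat(sprintf("  horizon: %g y x %g d; escalation at day %g\n",
              x$horizon_years, x$days_per_year, x$escalation_day))
  cat(sprintf("  u_base %.6g, u_fail %.6g; discount %s (r = %g)\n",
              x$u_base, x$u_fail, x$discount_mode, x$discount_rate))
  cat(sprintf("  WTP: %s x GDP %s\n",
              paste(x$wtp_multipliers, collapse = "/"),
              format(x$gdp_per_capita, big.mark = ",", scientific = FALSE)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
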