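## Result serialization: per-strategy and pairwise-comparison tables written
## as CSV/JSON with fixed column order and fixed number formatting, so
## identical inputs produce byte-identical files (no timestamps in data
## files). Utilities and QALYs print to 8 decimals, currencies as integers
## (probability-weighted expected values to 1 decimal).

fmt_u <- function(x) formatC(x, format = "f", digits = 8)
fmt_c <- function(x) {
  r <- round_half_away(x, 1)
  ifelse(is.na(x), NA_character_,
         ifelse(r == trunc(r), formatC(r, format = "d"),
                formatC(r, format = "f", digits = 1)))
}

#' Content fingerprint of a scenario
#'
#' Stable hash of the model-relevant fields (display-only fields excluded),
#' used to tie result files back to the exact parameterisation that produced
#' them.
#'
#' @param config A `cua_scenario`.
#' @return A hash string.
#' @export
scenario_fingerprint <- function(config) {
  rlang::hash(list(
    strategies = lapply(unname(config$strategies), function(s) list(
      s$name, s$initial$daily_price, s$initial$p_attain,
      s$escalated$daily_price, s$escalated$p_attain)),
    monitoring = unclass(config$monitoring),
    horizon_years = config$horizon_years, days_per_year = config$days_per_year,
    escalation_day = config$escalation_day,
    u_base = config$u_base, u_fail = config$u_fail,
    p_complication = config$p_complication,
    discount_rate = config$discount_rate, discount_mode = config$discount_mode,
    gdp_per_capita = config$gdp_per_capita,
    wtp_multipliers = config$wtp_multipliers,
    downstream_branch_costs = config$downstream_branch_costs))
}

write_atomic <- function(write_fun, path) {
  tmp <- paste0(path, ".tmp")
  ok <- FALSE
  on.exit(if (!ok) unlink(tmp) else invisible(file.rename(tmp, path)), add = TRUE)
  write_fun(tmp)
  ok <- TRUE
  invisible(path)
}

format_strategy_rows <- function(results) {
  tab <- strategy_table(results)
  data.frame(strategy = tab$strategy,
             cost_no_escalation = fmt_c(tab$cost_no_escalation),
             cost_escalation = fmt_c(tab$cost_escalation),
             expected_cost = fmt_c(tab$expected_cost),
             overall_attainment = fmt_u(tab$overall_attainment),
             total_utility = fmt_u(tab$total_utility),
             qaly = fmt_u(tab$qaly),
             lyg = formatC(tab$lyg, format = "fg"))
}

format_comparison_rows <- function(comparisons) {
  do.call(rbind, lapply(comparisons, function(cmp) data.frame(
    intervention = cmp$intervention_name,
    comparator = cmp$comparator_name,
    delta_cost = fmt_c(cmp$delta_cost),
    delta_qaly = fmt_u(cmp$delta_qaly),
    icer = if (is.na(cmp$icer)) "undefined" else fmt_c(round_half_away(cmp$icer)),
    quadrant = cmp$quadrant,
    dominance = cmp$dominance,
    wtp_band = cmp$wtp_band,
    verdict = cmp$verdict,
    mode = cmp$mode)))
}

#' Run a scenario end to end and write the result tables
#'
#' Evaluates every strategy, forms the requested pairwise comparisons, and
#' writes `strategies.{csv,json}` and `comparisons.{csv,json}` under
#' `out_dir`. On any failure, partially written files are removed.
#'
#' @param scenario A `cua_scenario`, or a path to a scenario document.
#' @param comparisons List of `c(intervention, comparator)` name pairs; the
#'   default compares the first strategy against each of the others.
#' @param out_dir Output directory (created if missing); `NULL` to skip file
#'   output.
#' @param formats Subset of `c("csv", "json")`.
#' @param mode Banding mode, see [classify()].
#' @param totals_override Optional externally reported totals, see
#'   [compare_strategies()]. Accepts a data frame or a path to a JSON/YAML
#'   file with columns/fields `strategy`, `total_cost`, `total_qaly`.
#' @param verbose Log scenario hash, mode and verdicts to stderr.
#' @return A `cua_run_report`: list with `fingerprint`, `strategies` and
#'   `comparisons` data frames, `files`, `version`, `timestamp`.
#' @export
run_report <- function(scenario, comparisons = NULL, out_dir = NULL,
                       formats = c("csv", "json"),
                       mode = c("paper_compatible", "quadrant_aware"),
                       totals_override = NULL, verbose = FALSE) {
  mode <- match.arg(mode)
  formats <- match.arg(formats, several.ok = TRUE)
  if (is.character(scenario)) scenario <- load_scenario(scenario)
  if (is.character(totals_override) && length(totals_override) == 1L) {
    raw <- yaml::read_yaml(totals_override)
    totals_override <- do.call(rbind, lapply(raw, as.data.frame))
  }
  nms <- names(scenario$strategies)
  if (is.null(comparisons)) {
    comparisons <- lapply(nms[-1], function(b) c(nms[1], b))
  }
  for (pair in comparisons) {
    missing <- setdiff(pair, nms)
    if (length(missing))
      stop("unknown strategy name in comparisons: ",
           paste(missing, collapse = ", "), call. = FALSE)
  }
  results <- evaluate_scenario(scenario)
  cmps <- lapply(comparisons, function(pair)
    compare_strategies(scenario, pair[1], pair[2], mode = mode,
                       totals_override = totals_override))
  strat_rows <- format_strategy_rows(results)
  cmp_rows <- format_comparison_rows(cmps)
  fp <- scenario_fingerprint(scenario)
  if (verbose) {
    message("scenario ", fp, " mode=", mode)
    for (cmp in cmps)
      message(cmp$intervention_name, " vs ", cmp$comparator_name, ": ", cmp$verdict)
  }

  files <- character()
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    emit <- function(df, stem) {
      if ("csv" %in% formats) {
        f <- file.path(out_dir, paste0(stem, ".csv"))
        write_atomic(function(p) utils::write.csv(df, p, row.names = FALSE,
                                                  quote = TRUE), f)
        files <<- c(files, f)
      }
      if ("json" %in% formats) {
        f <- file.path(out_dir, paste0(stem, ".json"))
        write_atomic(function(p) jsonlite::write_json(df, p, dataframe = "rows",
                                                      pretty = TRUE), f)
        files <<- c(files, f)
      }
    }
    emit(strat_rows, "strategies")
    emit(cmp_rows, "comparisons")
  }

  structure(list(fingerprint = fp, strategies = strat_rows,
                 comparisons = cmp_rows, files = files,
                 version = as.character(utils::packageVersion("cuatree")),
                 timestamp = format(Sys.time(), tz = "UTC")),
            class = "cua_run_report")
}

#' @export
print.cua_run_report <- function(x, ...) {
  cat("<cua_run_report>", x$fingerprint, "(cuatree", paste0(x$version, ")"), "\n")
  print(x$strategies, row.names = FALSE)
  print(x$comparisons, row.names = FALSE)
  invisible(x)
}

#' One-way sensitivity analysis with CSV table and tornado chart
#'
#' Runs [one_way()] for one strategy pair, orders the entries, writes
#' `tornado_<intervention>_vs_<comparator>.csv` (columns: parameter, base,
#' low, high, pct_low, pct_high, range) and, when a chart format is given,
#' the matching tornado diagram.
#'
#' @param scenario A `cua_scenario` or a path to a scenario document.
#' @param intervention,comparator Strategy names.
#' @param parameter_paths Paths to vary; default [default_tornado_parameters()].
#' @param fraction Perturbation fraction (default 0.20).
#' @param out_dir Output directory.
#' @param chart_format `"svg"`, `"png"`, or `NULL` for no chart.
#' @param mode Banding mode.
#' @return The ordered `cua_tornado` data frame, with attribute `"files"`.
#' @export
tornado_report <- function(scenario, intervention, comparator,
                           parameter_paths = NULL, fraction = 0.20,
                           out_dir = NULL, chart_format = "png",
                           mode = c("paper_compatible", "quadrant_aware")) {
  mode <- match.arg(mode)
  if (is.character(scenario)) scenario <- load_scenario(scenario)
  if (is.null(parameter_paths))
    parameter_paths <- default_tornado_parameters(scenario)
  entries <- tornado_order(one_way(scenario, intervention, comparator,
                                   parameter_paths, fraction, mode = mode))
  files <- character()
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    stem <- paste0("tornado_", intervention, "_vs_", comparator)
    csv <- file.path(out_dir, paste0(stem, ".csv"))
    out_tab <- data.frame(parameter = entries$parameter,
                          base = entries$base_icer,
                          low = entries$low_icer, high = entries$high_icer,
                          pct_low = entries$pct_change_low,
                          pct_high = entries$pct_change_high,
                          range = entries$range)
    write_atomic(function(p) utils::write.csv(out_tab, p, row.names = FALSE), csv)
    files <- c(files, csv)
    if (!is.null(chart_format) && nrow(entries)) {
      chart <- file.path(out_dir, paste0(stem, ".", chart_format))
      write_atomic(function(p) render_tornado(entries, p, chart_format,
                                              title = paste0("ICER sensitivity: ",
                                                             intervention, " vs ",
                                                             comparator)),
                   chart)
      files <- c(files, chart)
    }
  }
  attr(entries, "files") <- files
  entries
}

#' Read a tornado CSV back into a `cua_tornado` data frame
#'
#' Inverse of the CSV written by [tornado_report()].
#'
#' @param path CSV file path.
#' @return A `cua_tornado` data frame with [one_way()] column names.
#' @export
read_tornado <- function(path) {
  raw <- utils::read.csv(path)
  out <- data.frame(parameter = raw$parameter, base_icer = raw$base,
                    low_icer = raw$low, high_icer = raw$high,
                    pct_change_low = raw$pct_low, pct_change_high = raw$pct_high,
                    range = raw$range)
  class(out) <- c("cua_tornado", class(out))
  out
}

#' Calibrate the fail-branch utility from a scenario strategy's reported
#' total
#'
#' Convenience wrapper around [calibrate_fail_utility()] taking the base
#' utility and attainment probabilities from a scenario.
#'
#' @param scenario A `cua_scenario` or a path to a scenario document.
#' @param strategy_name Strategy whose reported total is supplied.
#' @param printed_total_utility The reported total utility.
#' @return The implied `u_fail`.
#' @export
calibrate_scenario <- function(scenario, strategy_name, printed_total_utility) {
  if (is.character(scenario)) scenario <- load_scenario(scenario)
  if (!strategy_name %in% names(scenario$strategies))
    stop("unknown strategy: ", strategy_name, call. = FALSE)
  s <- scenario$strategies[[strategy_name]]
  calibrate_fail_utility(printed_total_utility, scenario$u_base,
                         s$initial$p_attain, s$escalated$p_attain)
}
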