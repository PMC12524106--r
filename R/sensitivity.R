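## One-way deterministic sensitivity analysis: perturb one scenario
## parameter at a time by a fixed fraction and chart the ICER swings.

## Resolve a dotted parameter path (e.g. "strategies.pitavastatin.initial.
## daily_price", "monitoring.test_unit_cost", "u_base") inside a scenario.
## Strategy names act as keys under "strategies"; branch names under
## "downstream_branch_costs".
path_get <- function(config, parts) {
  node <- config
  for (p in parts) {
    if (is.null(node[[p]]))
      stop("unknown parameter path component: ", p, call. = FALSE)
    node <- node[[p]]
  }
  node
}

path_set <- function(node, parts, value) {
  if (length(parts) == 1L) {
    node[[parts]] <- value
    return(node)
  }
  node[[parts[1]]] <- path_set(node[[parts[1]]], parts[-1], value)
  node
}

#' Return a copy of a scenario with one numeric parameter scaled
#'
#' The parameter addressed by `parameter_path` (dotted notation, e.g.
#' `"strategies.pitavastatin.initial.daily_price"` or `"u_base"`) is
#' multiplied by `factor`. Probabilities and utilities are clamped back into
#' their valid ranges with a warning (`u_fail` additionally capped at
#' `u_base`, and `u_base` floored at `u_fail`), so the returned scenario
#' always validates. The input scenario is never modified.
#'
#' @param config A `cua_scenario`.
#' @param parameter_path Dotted path to a numeric scalar.
#' @param factor Positive multiplier.
#' @return A new validated `cua_scenario`.
#' @export
perturb <- function(config, parameter_path, factor) {
  stopifnot(is.numeric(factor), length(factor) == 1L, factor > 0)
  parts <- strsplit(parameter_path, ".", fixed = TRUE)[[1]]
  old <- path_get(config, parts)
  if (!is.numeric(old) || length(old) != 1L)
    stop("parameter path does not resolve to a numeric scalar: ",
         parameter_path, call. = FALSE)
  value <- old * factor

  leaf <- parts[length(parts)]
  clamp <- function(v, lo, hi) {
    if (v < lo || v > hi) {
      warning(sprintf("perturbed %s = %g clamped to [%g, %g]",
                      parameter_path, v, lo, hi), call. = FALSE)
      v <- min(max(v, lo), hi)
    }
    v
  }
  if (leaf %in% c("p_attain", "p_complication")) {
    value <- clamp(value, 0, 1)
  } else if (leaf == "u_base") {
    value <- clamp(value, config$u_fail, 1)
  } else if (leaf == "u_fail") {
    value <- clamp(value, 0, config$u_base)
  }

  out <- path_set(config, parts, value)
  class(out) <- class(config)
  v <- validate_scenario(out)
  if (nrow(v) > 0)
    stop("perturbation produced an invalid scenario:\n",
         paste0("  ", v$field, ": ", v$rule, collapse = "\n"), call. = FALSE)
  out
}

#' Default parameter set for the tornado analysis
#'
#' Every daily drug price, every attainment probability, the laboratory test
#' unit cost, both utility weights, and any nonzero downstream branch cost.
#'
#' @param config A `cua_scenario`.
#' @return Character vector of dotted parameter paths.
#' @export
default_tornado_parameters <- function(config) {
  paths <- character()
  for (nm in names(config$strategies)) {
    for (side in c("initial", "escalated")) {
      paths <- c(paths,
                 paste0("strategies.", nm, ".", side, ".daily_price"),
                 paste0("strategies.", nm, ".", side, ".p_attain"))
    }
  }
  paths <- c(paths, "monitoring.test_unit_cost", "u_base", "u_fail")
  dbc <- config$downstream_branch_costs
  nonzero <- names(dbc)[which(dbc > 0)]
  if (length(nonzero))
    paths <- c(paths, paste0("downstream_branch_costs.", nonzero))
  paths
}

#' One-way deterministic sensitivity analysis of a pairwise ICER
#'
#' For each parameter path, re-evaluates the comparison with the parameter
#' scaled to `1 - fraction` and `1 + fraction` of its base value and records
#' the resulting ICERs. The base ICER is computed once from the unperturbed
#' scenario. A perturbation under which the QALY difference vanishes
#' (absolute difference below 1e-9 QALYs, which also absorbs floating-point
#' residue when clamping collapses the two utility weights onto each other)
#' yields `NA` ICER entries rather than a fabricated ratio. Percent changes are `(perturbed - base) / |base| * 100`, so the
#' sign is meaningful even when the base ICER is negative.
#'
#' @param config A `cua_scenario`.
#' @param intervention,comparator Strategy names in `config`.
#' @param parameter_paths Paths to vary; default [default_tornado_parameters()].
#' @param fraction Perturbation fraction (default 0.20).
#' @param mode Banding mode passed through to [compare_strategies()].
#' @param totals_override Optional totals override, see [compare_strategies()];
#'   overridden strategies keep their reported totals under perturbation, so
#'   overrides are normally used only for the base comparison.
#' @return A `cua_tornado` data frame: `parameter`, `base_icer`, `low_icer`,
#'   `high_icer`, `pct_change_low`, `pct_change_high`, `range`.
#' @export
one_way <- function(config, intervention, comparator,
                    parameter_paths = default_tornado_parameters(config),
                    fraction = 0.20,
                    mode = c("paper_compatible", "quadrant_aware"),
                    totals_override = NULL) {
  mode <- match.arg(mode)
  icer_of <- function(cfg) {
    cmp <- compare_strategies(cfg, intervention, comparator, mode = mode,
                              totals_override = totals_override)
    ## a QALY difference at floating-point noise level (e.g. after clamping
    ## u_base onto u_fail both strategies share one utility) has no
    ## meaningful ICER: flag undefined instead of a huge fabricated ratio
    if (is.na(cmp$icer) || abs(cmp$delta_qaly) < 1e-9) NA_real_ else cmp$icer
  }
  base <- icer_of(config)
  pct <- function(x) (x - base) / abs(base) * 100
  rows <- lapply(parameter_paths, function(pp) {
    lo <- icer_of(perturb(config, pp, 1 - fraction))
    hi <- icer_of(perturb(config, pp, 1 + fraction))
    data.frame(parameter = pp, base_icer = base, low_icer = lo, high_icer = hi,
               pct_change_low = pct(lo), pct_change_high = pct(hi),
               range = abs(hi - lo))
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(parameter = character(), base_icer = numeric(),
               low_icer = numeric(), high_icer = numeric(),
               pct_change_low = numeric(), pct_change_high = numeric(),
               range = numeric())
  class(out) <- c("cua_tornado", class(out))
  out
}

#' Order tornado entries by decreasing ICER swing
#'
#' Stable sort on `range`, largest first; ties broken lexicographically by
#' parameter path; undefined ranges (`NA`) sort last.
#'
#' @param entries A `cua_tornado` data frame.
#' @return The reordered data frame.
#' @export
tornado_order <- function(entries) {
  if (!nrow(entries)) return(entries)
  ord <- order(-xtfrm(entries$range), entries$parameter, na.last = TRUE)
  out <- entries[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Render a tornado diagram
#'
#' Horizontal paired bars anchored at the base ICER: orange for the
#' parameter decreased by the perturbation fraction, blue for the parameter
#' increased, parameters ordered top-down by swing. Entries with undefined
#' ICERs are dropped from the chart.
#'
#' @param entries A `cua_tornado` data frame (see [one_way()]).
#' @param output_path File to write.
#' @param format `"svg"` or `"png"`.
#' @param title Optional chart title.
#' @return `output_path`, invisibly. The ggplot object is attached as
#'   attribute `"plot"`.
#' @export
render_tornado <- function(entries, output_path, format = c("svg", "png"),
                           title = "One-way sensitivity of the ICER") {
  format <- match.arg(format)
  entries <- tornado_order(entries)
  entries <- entries[!is.na(entries$range), , drop = FALSE]
  if (!nrow(entries)) stop("no defined tornado entries to render", call. = FALSE)

  base <- entries$base_icer[1]
  long <- rbind(
    data.frame(parameter = entries$parameter, value = entries$low_icer,
               direction = "decreased", offset = 0.17),
    data.frame(parameter = entries$parameter, value = entries$high_icer,
               direction = "increased", offset = -0.17))
  ## bottom-up factor order so the largest swing renders on top
  long$parameter <- factor(long$parameter, levels = rev(entries$parameter))
  long$y <- as.numeric(long$parameter) + long$offset

  p <- ggplot2::ggplot(long) +
    ggplot2::geom_segment(
      ggplot2::aes(x = base, xend = .data$value, y = .data$y, yend = .data$y,
                   colour = .data$direction),
      linewidth = 4, lineend = "butt") +
    ggplot2::geom_vline(xintercept = base, linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(decreased = "#E69F00",
                                            increased = "#2166AC"),
                                 name = "parameter value") +
    ggplot2::scale_y_continuous(breaks = seq_len(nlevels(long$parameter)),
                                labels = levels(long$parameter)) +
    ggplot2::labs(x = "ICER (currency per QALY)", y = NULL, title = title) +
    ggplot2::theme_minimal()

  dev <- switch(format,
                svg = function(f) grDevices::svg(f, width = 9, height = 1 + 0.45 * nrow(entries)),
                png = function(f) grDevices::png(f, width = 1800,
                                                 height = 200 + 90 * nrow(entries), res = 200))
  dev(output_path)
  on.exit(grDevices::dev.off(), add = TRUE)
  print(p)
  invisible(structure(output_path, plot = p))
}
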