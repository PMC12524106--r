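#!/usr/bin/env Rscript
# Step 3 — one-way deterministic sensitivity analysis (+/-20%) of both
# pairwise ICERs over every price, attainment probability, the test cost
# and both utility weights; tornado CSVs and charts go to results/.
#
# Perturbations that drive the QALY difference to zero (e.g. u_fail rising
# to u_base) yield undefined ICER entries, kept as NA in the tables and
# dropped from the charts.

library(cuatree)

cfg <- builtin_scenario("vietnam_dyslipidemia_2024")

for (comparator in c("atorvastatin", "rosuvastatin")) {
  cat("\n=== pitavastatin vs", comparator, "===\n")
  entries <- suppressWarnings(
    tornado_report(cfg, "pitavastatin", comparator,
                   fraction = 0.20, out_dir = "results",
                   chart_format = "png"))
  print(utils::head(entries[, c("parameter", "low_icer", "high_icer", "range")], 8),
        row.names = FALSE)
  top <- entries$parameter[!is.na(entries$range)][1]
  cat("most influential parameter:", top, "\n")
  cat("files:", paste(attr(entries, "files"), collapse = ", "), "\n")
}
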