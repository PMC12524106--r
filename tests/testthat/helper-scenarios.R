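# Shared fixtures: the packaged Vietnam scenario plus a tiny hand-rolled
# two-strategy scenario whose numbers are simple enough to check by hand.

vn <- builtin_scenario("vietnam_dyslipidemia_2024")
vn_ref <- builtin_reference_totals("vietnam_dyslipidemia_2024")

toy_scenario <- function(...) {
  args <- utils::modifyList(
    list(
      strategies = list(
        strategy("a",
                 dose_arm("a low", 100, 0.5),
                 dose_arm("a high", 200, 0.5)),
        strategy("b",
                 dose_arm("b low", 150, 0.6),
                 dose_arm("b high", 150, 0.7))),
      monitoring = monitoring_plan(tests_per_panel = 2, test_unit_cost = 10,
                                   panels_if_no_escalation = 1,
                                   panels_if_escalation = 2),
      horizon_years = 1, days_per_year = 10, escalation_day = 4,
      u_base = 0.9, u_fail = 0.6, gdp_per_capita = 1000),
    list(...))
  do.call(scenario_config, args)
}
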