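# Vietnam 2024 dyslipidemia scenario: two-stage statin dose-escalation tree.
# All currency values are integer VND; probabilities and utilities are decimals.
# u_fail is calibrated so that the model's total strategy utilities match the
# reported values for this scenario (single free parameter, solved in closed
# form from the atorvastatin strategy; see cuatree::calibrate_fail_utility).
name: vietnam_dyslipidemia_2024
strategies:
  - name: pitavastatin
    initial:   {label: "pitavastatin 2 mg", daily_price: 13500, p_attain: 0.717}
    escalated: {label: "pitavastatin 4 mg", daily_price: 18500, p_attain: 0.796}
  - name: atorvastatin
    initial:   {label: "atorvastatin 10 mg", daily_price: 15941, p_attain: 0.777}
    escalated: {label: "atorvastatin 20 mg", daily_price: 15941, p_attain: 0.817}
  - name: rosuvastatin
    initial:   {label: "rosuvastatin 5 mg", daily_price: 8978, p_attain: 0.759}
    escalated: {label: "rosuvastatin 10 mg", daily_price: 14553, p_attain: 0.800}
monitoring:
  tests_per_panel: 4          # TC, HDL-C, LDL-C, TG
  test_unit_cost: 27300
  panels_if_no_escalation: 2
  panels_if_escalation: 3
horizon_years: 14             # life expectancy 75 minus cohort mean age 61
days_per_year: 365
escalation_day: 56            # LDL-C reassessment at 8 weeks
u_base: 0.8255
u_fail: 0.70789996
p_complication: 0.145
discount_rate: 0.03
discount_mode: none
gdp_per_capita: 114000000
wtp_multipliers: [1, 3]
usd_exchange_rate: 24164.89   # display only, never used in arithmetic
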