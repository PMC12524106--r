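# Reported per-strategy totals accompanying the Vietnam 2024 scenario.
# total_utility follows from the tree inputs alone; total_cost and total_qaly
# additionally include downstream components (lifetime complication costs,
# age-stratified utility adjustments) that are not part of the published
# drug/monitoring inputs, so they are carried here as externally reported
# totals for use as a totals override in incremental analyses.
name: vietnam_dyslipidemia_2024
strategies:
  pitavastatin:
    total_utility: 0.81871072
    total_qaly: 11.12292411
    total_cost: 1062525311
  atorvastatin:
    total_utility: 0.82070086
    total_qaly: 11.28300399
    total_cost: 1093805451
  rosuvastatin:
    total_utility: 0.81983168
    total_qaly: 11.19477268
    total_cost: 973277353
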