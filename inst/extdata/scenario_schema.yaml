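# Machine-readable schema for cuatree scenario documents (YAML or JSON).
# Unknown keys anywhere in a document are rejected. "required: false" fields
# take the stated default when omitted. Currency values are integer VND;
# probabilities and utilities are plain decimals in [0, 1], never percent.
schema_version: 1
root:
  name:           {type: string,  required: false, default: null}
  strategies:     {type: list of strategy, required: true, min_length: 1}
  monitoring:     {type: monitoring, required: true}
  horizon_years:  {type: number,  required: false, default: 14, constraint: "> 0"}
  days_per_year:  {type: integer, required: false, default: 365, constraint: "> 0"}
  escalation_day: {type: integer, required: false, default: 56,
                   constraint: "0 <= escalation_day < horizon_years * days_per_year"}
  u_base:         {type: number,  required: true,  constraint: "0 <= u_fail <= u_base <= 1"}
  u_fail:         {type: number,  required: true,  constraint: "0 <= u_fail <= u_base <= 1"}
  p_complication: {type: number,  required: false, default: null, constraint: "in [0, 1]"}
  discount_rate:  {type: number,  required: false, default: 0.03, constraint: ">= 0"}
  discount_mode:  {type: enum [none, annual_annuity], required: false, default: none}
  gdp_per_capita: {type: number,  required: true,  constraint: "> 0"}
  wtp_multipliers: {type: pair of numbers, required: false, default: [1, 3],
                    constraint: "0 < first <= second"}
  downstream_branch_costs:
    type: map {ACHIEVE_INITIAL: currency, ACHIEVE_ESCALATED: currency, FAIL: currency}
    required: false
    default: {ACHIEVE_INITIAL: 0, ACHIEVE_ESCALATED: 0, FAIL: 0}
    constraint: "all >= 0"
  usd_exchange_rate: {type: number, required: false, default: null,
                      note: "display only", constraint: "> 0"}
strategy:
  name:      {type: string, required: true, note: "unique within the document"}
  initial:   {type: dose_arm, required: true}
  escalated: {type: dose_arm, required: true}
dose_arm:
  label:       {type: string, required: false, default: ""}
  daily_price: {type: currency, required: true, constraint: ">= 0"}
  p_attain:    {type: number,   required: true, constraint: "in [0, 1]"}
monitoring:
  tests_per_panel:         {type: integer,  required: false, default: 4, constraint: ">= 0"}
  test_unit_cost:          {type: currency, required: true,  constraint: ">= 0"}
  panels_if_no_escalation: {type: integer,  required: false, default: 2, constraint: ">= 0"}
  panels_if_escalation:    {type: integer,  required: false, default: 3, constraint: ">= 0"}
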