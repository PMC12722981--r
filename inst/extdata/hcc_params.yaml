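# Model input bundle: advanced HCC first line, toripalimab + bevacizumab vs
# sorafenib. All monetary values are 2024 USD (converted at 1 USD = 7.1217 RMB
# by the source analysis; the exchange rate is metadata only, nothing here is
# converted at run time). Time unit for survival parameters is months.
# Each uncertain parameter carries value/low/high and the sampling family used
# in probabilistic sensitivity analysis (gamma for costs and weight, beta for
# probabilities, utilities and disutilities; fixed = not sampled).
label: "Advanced HCC first line: toripalimab + bevacizumab vs sorafenib"
currency: USD
usd_per_rmb_metadata: 7.1217
weight_kg: {value: 65, low: 52, high: 78, dist: gamma}
discount_rate: {value: 0.05, low: 0.00, high: 0.08, dist: fixed}
wtp_per_qaly: 40334          # 3x China 2024 per-capita GDP
gdp_per_capita: 13445

survival:   # log-normal fits selected by AIC/BIC for both endpoints, both arms
  combo:
    os:  {family: log-normal, meanlog: 2.9363, sdlog: 1.1358}
    pfs: {family: log-normal, meanlog: 1.6667, sdlog: 1.1352}
  sorafenib:
    os:  {family: log-normal, meanlog: 2.6781, sdlog: 1.0775}
    pfs: {family: log-normal, meanlog: 1.3500, sdlog: 0.8960}

drugs:
  toripalimab:
    unit_mg: 240
    unit_cost: {value: 264.66, low: 211.73, high: 317.59, dist: gamma}
    dose_rule: fixed_mg_per_cycle
    dose_value: 240          # 240 mg every 3 weeks
    iv: true
    max_cycles: 35           # trial cap
  bevacizumab:
    unit_mg: 100
    unit_cost: {value: 155.02, low: 134.38, high: 210.62, dist: gamma}
    dose_rule: mg_per_kg_per_cycle
    dose_value: 15           # 15 mg/kg every 3 weeks
    iv: true
    max_cycles: 35           # first-line stopping convention, see vignette
  sorafenib:
    unit_mg: 200
    unit_cost: {value: 3.38, low: 0.70, high: 12.54, dist: gamma}
    dose_rule: mg_per_day
    dose_value: 800          # 400 mg twice daily
    iv: false
  regorafenib:
    unit_mg: 40
    unit_cost: {value: 7.62, low: 0.59, high: 24.22, dist: gamma}
    dose_rule: mg_per_day
    dose_value: 160
    days_on_fraction: 0.75   # 160 mg/day on days 1-21 of a 28-day cycle
    iv: false
  pembrolizumab:
    unit_mg: 100
    unit_cost: {value: 2515.97, low: 2012.78, high: 3019.16, dist: gamma}
    dose_rule: fixed_mg_per_cycle
    dose_value: 200          # labeled flat dose every 3 weeks
    iv: true

costs:
  bsc_per_cycle:               {value: 366.63,  low: 293.30,  high: 439.96,  dist: gamma}
  followup_pfs_per_cycle:      {value: 83.13,   low: 66.50,   high: 99.76,   dist: gamma}
  followup_pd_per_cycle:       {value: 153.05,  low: 122.44,  high: 183.66,  dist: gamma}
  administration_per_infusion: {value: 17.69,   low: 14.15,   high: 21.23,   dist: gamma}
  end_of_life:                 {value: 1914.99, low: 1531.99, high: 2297.99, dist: gamma}

# Grade >= 3 adverse events with incidence above 5% in either arm.
# Management cost is per event; disutility is a one-off QALY decrement applied
# (x incidence) in the first model cycle.
adverse_events:
  - name: anaemia
    cost:       {value: 605.33, low: 484.26, high: 726.40, dist: gamma}
    disutility: {value: 0.073,  low: 0.058,  high: 0.088,  dist: beta}
    incidence:
      combo:     {value: 0.06, low: 0.05, high: 0.07, dist: beta}
      sorafenib: {value: 0.04, low: 0.03, high: 0.05, dist: beta}
  - name: hypertension
    cost:       {value: 35.53, low: 28.42, high: 42.64, dist: gamma}
    disutility: {value: 0.016, low: 0.013, high: 0.019, dist: beta}
    incidence:
      combo:     {value: 0.16, low: 0.13, high: 0.19, dist: beta}
      sorafenib: {value: 0.12, low: 0.10, high: 0.14, dist: beta}
  - name: proteinuria
    cost:       {value: 106.29, low: 85.03, high: 127.55, dist: gamma}
    disutility: {value: 0.12,   low: 0.096, high: 0.144,  dist: beta}
    incidence:
      combo:     {value: 0.05, low: 0.04,  high: 0.06,  dist: beta}
      sorafenib: {value: 0.01, low: 0.008, high: 0.012, dist: beta}
  - name: thrombocytopenia
    cost:       {value: 3434.29, low: 2747.43, high: 4121.15, dist: gamma}
    disutility: {value: 0.05,    low: 0.04,    high: 0.06,    dist: beta}
    incidence:
      combo:     {value: 0.10, low: 0.08, high: 0.12, dist: beta}
      sorafenib: {value: 0.03, low: 0.02, high: 0.04, dist: beta}
  - name: ast_increased
    cost:       {value: 180.02, low: 144.02, high: 216.02, dist: gamma}
    disutility: {value: 0.0, dist: fixed}
    incidence:
      combo:     {value: 0.01, low: 0.008, high: 0.012, dist: beta}
      sorafenib: {value: 0.05, low: 0.04,  high: 0.06,  dist: beta}
  - name: bilirubin_increased
    cost:       {value: 107.70, low: 86.16, high: 129.24, dist: gamma}
    disutility: {value: 0.0, dist: fixed}
    incidence:
      combo:     {value: 0.05, low: 0.04, high: 0.06, dist: beta}
      sorafenib: {value: 0.03, low: 0.02, high: 0.04, dist: beta}
  - name: alt_increased
    cost:       {value: 89.02, low: 71.22, high: 106.82, dist: gamma}
    disutility: {value: 0.0, dist: fixed}
    incidence:
      combo:     {value: 0.01, low: 0.008, high: 0.012, dist: beta}
      sorafenib: {value: 0.05, low: 0.04,  high: 0.06,  dist: beta}
  - name: diarrhoea
    cost:       {value: 195.74, low: 156.59, high: 234.89, dist: gamma}
    disutility: {value: 0.05,   low: 0.04,   high: 0.06,   dist: beta}
    incidence:
      combo:     {value: 0.01, low: 0.008, high: 0.012, dist: beta}
      sorafenib: {value: 0.07, low: 0.06,  high: 0.08,  dist: beta}
  - name: ppe   # palmar-plantar erythrodysaesthesia
    cost:       {value: 16.96, low: 13.57, high: 20.35, dist: gamma}
    disutility: {value: 0.15,  low: 0.12,  high: 0.18,  dist: beta}
    incidence:
      combo:     {value: 0.0, dist: fixed}
      sorafenib: {value: 0.10, low: 0.08, high: 0.12, dist: beta}

# Disposition after progression. bsc = 1 - p_any_systemic (holds exactly in
# both arms). The targeted/immunotherapy rows overlap p_any_systemic because
# trial patients could receive several lines; see share_mode in the config.
subsequent:
  combo:
    p_any_systemic: {value: 0.568, low: 0.454, high: 0.682, dist: beta}
    targeted:       {value: 0.475, low: 0.380, high: 0.570, dist: beta}
    immunotherapy:  {value: 0.272, low: 0.218, high: 0.326, dist: beta}
    bsc:            {value: 0.432, low: 0.346, high: 0.518, dist: beta}
  sorafenib:
    p_any_systemic: {value: 0.689, low: 0.551, high: 0.827, dist: beta}
    targeted:       {value: 0.579, low: 0.463, high: 0.695, dist: beta}
    immunotherapy:  {value: 0.445, low: 0.356, high: 0.534, dist: beta}
    bsc:            {value: 0.311, low: 0.249, high: 0.373, dist: beta}

utilities:
  pfs: {value: 0.76, low: 0.61, high: 0.91, dist: beta}
  pd:  {value: 0.68, low: 0.54, high: 0.82, dist: beta}
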