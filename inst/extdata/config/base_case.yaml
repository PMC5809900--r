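# Base-case inputs: adults aged 50 and older, two-year screening cycle,
# 10-year horizon. Bracketed alternatives for the one-way sensitivity
# analysis live under `univariate`. Costs in 2013 euros, doses in uSv.
scenario: base_case
cycle_length: 2
horizon: 10
discount_rate: 0.05
asymptomatic_ratio: 2.8
cohort_size: 1000
women:
  vf_prevalence: 0.22
  vf_incidence: 0.12
  new_vf_incidence: 0.22
  rr_treatment: 0.58
  vfa_sensitivity: 0.82
  vfa_specificity: 0.93
  p_vfa_unreadable: 0.03
  xray_sensitivity: 1.0
  xray_specificity: 1.0
  cost_vfa: 17
  cost_xray: 24
  cost_vf_treatment: 1526
  cost_physician_visit: 9
  cost_drug_year: 180
  cost_procedure: 809
  dose_xray: 600
  dose_vfa: 25
  population_weight: 8649974
  univariate:
    vf_prevalence: 0.08
    vf_incidence: 0.13
    new_vf_incidence: 0.23
    rr_treatment: 0.64
    vfa_sensitivity: 0.74
    vfa_specificity: 0.89
    p_vfa_unreadable: 0.05
    cost_vfa: 40
    cost_xray: 17
    cost_vf_treatment: 1249
    dose_vfa: 2
men:
  vf_prevalence: 0.11
  vf_incidence: 0.05
  new_vf_incidence: 0.22
  rr_treatment: 0.38
  vfa_sensitivity: 0.82
  vfa_specificity: 0.93
  p_vfa_unreadable: 0.03
  xray_sensitivity: 1.0
  xray_specificity: 1.0
  cost_vfa: 17
  cost_xray: 24
  cost_vf_treatment: 1707
  cost_physician_visit: 9
  cost_drug_year: 194
  cost_procedure: 934
  dose_xray: 600
  dose_vfa: 25
  population_weight: 7590057
  univariate:
    vf_prevalence: 0.03
    vf_incidence: 0.05
    new_vf_incidence: 0.23
    rr_treatment: 0.41
    vfa_sensitivity: 0.74
    vfa_specificity: 0.89
    p_vfa_unreadable: 0.05
    cost_vfa: 40
    cost_xray: 17
    cost_vf_treatment: 1336
    dose_vfa: 2
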