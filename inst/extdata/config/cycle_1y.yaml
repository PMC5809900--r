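# Multivariate sensitivity analysis: one-year screening cycle with one-year
# incidence probabilities and the matching annual fracture treatment costs.
# All other inputs as in the base case.
scenario: cycle_1y
cycle_length: 1
horizon: 10
discount_rate: 0.05
asymptomatic_ratio: 2.8
cohort_size: 1000
women:
  vf_prevalence: 0.22
  vf_incidence: 0.06
  new_vf_incidence: 0.11
  rr_treatment: 0.58
  vfa_sensitivity: 0.82
  vfa_specificity: 0.93
  p_vfa_unreadable: 0.03
  xray_sensitivity: 1.0
  xray_specificity: 1.0
  cost_vfa: 17
  cost_xray: 24
  cost_vf_treatment: 1458
  cost_physician_visit: 9
  cost_drug_year: 180
  cost_procedure: 809
  dose_xray: 600
  dose_vfa: 25
  population_weight: 8649974
men:
  vf_prevalence: 0.11
  vf_incidence: 0.02
  new_vf_incidence: 0.11
  rr_treatment: 0.38
  vfa_sensitivity: 0.82
  vfa_specificity: 0.93
  p_vfa_unreadable: 0.03
  xray_sensitivity: 1.0
  xray_specificity: 1.0
  cost_vfa: 17
  cost_xray: 24
  cost_vf_treatment: 1509
  cost_physician_visit: 9
  cost_drug_year: 194
  cost_procedure: 934
  dose_xray: 600
  dose_vfa: 25
  population_weight: 7590057
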