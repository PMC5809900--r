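# Old-age subgroup: women aged 70 and older, men aged 80 and older.
# Two-year cycle; prevalence, incidences, treatment relative risk, VFA
# accuracy and fracture treatment cost specific to the subgroup; remaining
# inputs as in the base case.
scenario: subgroup_old_age
cycle_length: 2
horizon: 10
discount_rate: 0.05
asymptomatic_ratio: 2.8
cohort_size: 1000
women:
  vf_prevalence: 0.43
  vf_incidence: 0.29
  new_vf_incidence: 0.32
  rr_treatment: 0.60
  vfa_sensitivity: 0.88
  vfa_specificity: 0.99
  p_vfa_unreadable: 0.03
  xray_sensitivity: 1.0
  xray_specificity: 1.0
  cost_vfa: 17
  cost_xray: 24
  cost_vf_treatment: 1513
  cost_physician_visit: 9
  cost_drug_year: 180
  cost_procedure: 809
  dose_xray: 600
  dose_vfa: 25
  population_weight: 8649974
men:
  vf_prevalence: 0.46
  vf_incidence: 0.17
  new_vf_incidence: 0.32
  rr_treatment: 0.60
  vfa_sensitivity: 0.88
  vfa_specificity: 0.99
  p_vfa_unreadable: 0.03
  xray_sensitivity: 1.0
  xray_specificity: 1.0
  cost_vfa: 17
  cost_xray: 24
  cost_vf_treatment: 1675
  cost_physician_visit: 9
  cost_drug_year: 194
  cost_procedure: 934
  dose_xray: 600
  dose_vfa: 25
  population_weight: 7590057
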