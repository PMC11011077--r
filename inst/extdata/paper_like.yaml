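preset: paper_like
n_patients: 279
age_median: 62.0
age_q1: 55.0
age_q3: 68.0
age_min: 31.0
age_max: 85.0
p_female: 0.387096774193548
surgery_probs:
  biopsy: 0.254480286738351
  resection_100: 0.204301075268817
  resection_90: 0.308243727598566
  resection_lt90: 0.232974910394265
oncology_probs:
  no_stupp: 0.537634408602151
  full_stupp: 0.207885304659498
  partial_stupp: 0.254480286738351
p_mgmt_methylated_given_known: 0.39922480620155
p_mgmt_missing: 0.075268817204301
diameter_median: 4.4
diameter_q1: 3.3
diameter_q3: 5.4
cv_median: 28.100000000000001
cv_q1: 12.6
cv_q3: 50.299999999999997
wv_median: 103.299999999999997
wv_q1: 45.600000000000001
wv_q3: 160.099999999999994
size_copula_corr:
  diameter:
  - 1.0
  - 0.9
  - 0.8
  cv:
  - 0.9
  - 1.0
  - 0.85
  wv:
  - 0.8
  - 0.85
  - 1.0
surgery_size_assoc: 0.3
baseline_shape: 1.0
baseline_scale: 17.68
betas:
  log_wv: 0.22
  age: 0.01
  surgery_resection_100: -0.4
  surgery_resection_90: -0.25
  surgery_resection_lt90: -0.1
  oncology_full_stupp: -0.4
  oncology_partial_stupp: -0.2
  mgmt_methylated: -0.25
censor_lo: 13.0
censor_hi: 70.0
enforce_nesting: no
seed: 1
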