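diabetes_threshold: 1.0
criteria:
- name: icd9_encounter
  weight: 0.75
  accrual: per_distinct_date
  allowed_settings:
  - inpatient
  - outpatient
  code_prefix: '250'
- name: hba1c
  weight: 1.0
  accrual: per_distinct_date
  allowed_settings:
  - inpatient
  - outpatient
  threshold: 6.5
  units: '%'
- name: fasting_glucose
  weight: 0.5
  accrual: per_distinct_date
  allowed_settings: outpatient
  threshold: 126.0
  units: mg/dL
- name: random_glucose
  weight: 0.5
  accrual: per_distinct_date
  allowed_settings: outpatient
  threshold: 200.0
  units: mg/dL
- name: ogtt_2h
  weight: 0.75
  accrual: per_distinct_date
  allowed_settings:
  - inpatient
  - outpatient
  threshold: 200.0
  units: mg/dL
- name: history_dx
  weight: 0.4
  accrual: once_per_patient
  allowed_settings:
  - inpatient
  - outpatient
  code_prefix: '250'
- name: diabetes_medication
  weight: 1.0
  accrual: once_per_patient
  allowed_settings: outpatient
- name: metformin
  weight: 0.75
  accrual: once_per_patient
  allowed_settings: outpatient
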