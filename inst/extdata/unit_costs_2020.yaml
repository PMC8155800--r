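currency_year: 2020.0
resource_costs:
  emergency_visit: 144.24
  emergency_visit_observation: 392.03
  hospital_day: 495.59
  hospital_day_pneumology: 386.65
  spirometry: 40.57
  spirometry_bd: 60.49
  ige: 21.5
  feno: 39.0
  prick_test: 134.7
  haemogram: 5.3
  biochemistry: 83.5
  ct_non_contrast: 55.38
drugs:
  omalizumab:
    dose: 150 mg
    regimen: ~
    annual_cost: 17042.61
  mepolizumab:
    dose: 100 mg
    regimen:
      loading_doses: 0.0
      loading_interval_weeks: .na
      maintenance_interval_weeks: 4.0
    annual_cost: 10661.43
  benralizumab:
    dose: 30 mg
    regimen:
      loading_doses: 3.0
      loading_interval_weeks: 4.0
      maintenance_interval_weeks: 8.0
    annual_cost: 13762.64
ocs_course_5mg_eur: 11.86
ocs_course_30mg_eur: 23.73
ocs_course_eur: 23.73
ocs_mg_day_eur: 0.3388571
ics_pack_eur: 36.96
ics_pack_ug: 40000.0
admission_rate: hospital_day_pneumology
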