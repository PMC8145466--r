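# Predicted total energy requirement, kcal per kg body weight per day, by sex
# and age band (months, [lo, hi)), following the FAO/WHO framework (growth
# plus moderate physical activity). Requirement = kcal_per_kg x weight_kg.
# Editable defaults; bands must cover 9-25 months for both sexes.
rows:
  - {sex: M, lo_months: 9,  hi_months: 12, kcal_per_kg: 79.7}
  - {sex: M, lo_months: 12, hi_months: 25, kcal_per_kg: 82.4}
  - {sex: F, lo_months: 9,  hi_months: 12, kcal_per_kg: 79.3}
  - {sex: F, lo_months: 12, hi_months: 25, kcal_per_kg: 80.1}
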