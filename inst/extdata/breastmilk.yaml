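# Mature breast-milk composition. Energy density in kcal per gram of milk;
# nutrients per 100 g of milk in the pipeline's standard units. Editable
# defaults taken from published average values for mature human milk.
energy_kcal_per_g: 0.63
nutrients_per_100g:
  energy_kcal: 63
  thiamine_mg: 0.014
  riboflavin_mg: 0.035
  niacin_mg: 0.18
  vitB6_mg: 0.011
  folate_ug: 5
  vitB12_ug: 0.05
  vitA_ug: 60
  vitC_mg: 4
  vitD_ug: 0.07
  vitE_mg: 0.23
  calcium_mg: 26
  magnesium_mg: 3.4
  iron_mg: 0.03
  zinc_mg: 0.12
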