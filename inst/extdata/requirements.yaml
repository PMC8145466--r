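# Requirement distributions per nutrient x age bin (x zinc bioavailability
# class). Editable defaults following WHO/FAO recommended nutrient intakes
# (7-12 mo values for the 9-12 bin, 1-3 y values thereafter); replace with
# your study's table. Units match the nutrient column suffixes (mg/d, ug/d).
#
# kind: normal        -> requirement ~ Normal(ear, sd) with ear = rni/(1+2cv),
#                        sd = cv*ear (rni/cv given)
# kind: ai_threshold  -> PA = 1(eui >= ai)
# kind: quantile_table-> tabulated percentiles of the requirement distribution
#                        at reference_bioavailability; intakes are scaled by
#                        reference_bioavailability / assumed_bioavailability.
#                        The default iron grid is a SYNTHETIC lognormal
#                        approximation anchored at the published EAR (median)
#                        and RNI (97.5th percentile); it is illustrative and
#                        should be replaced by the authoritative table.
nutrients:
  thiamine_mg:
    "9-12":  {kind: normal, rni: 0.3, cv: 0.10}
    "13-16": {kind: normal, rni: 0.5, cv: 0.10}
    "17-20": {kind: normal, rni: 0.5, cv: 0.10}
    "21-24": {kind: normal, rni: 0.5, cv: 0.10}
  riboflavin_mg:
    "9-12":  {kind: normal, rni: 0.4, cv: 0.10}
    "13-16": {kind: normal, rni: 0.5, cv: 0.10}
    "17-20": {kind: normal, rni: 0.5, cv: 0.10}
    "21-24": {kind: normal, rni: 0.5, cv: 0.10}
  niacin_mg:
    "9-12":  {kind: normal, rni: 4.0, cv: 0.10}
    "13-16": {kind: normal, rni: 6.0, cv: 0.10}
    "17-20": {kind: normal, rni: 6.0, cv: 0.10}
    "21-24": {kind: normal, rni: 6.0, cv: 0.10}
  vitB6_mg:
    "9-12":  {kind: normal, rni: 0.3, cv: 0.10}
    "13-16": {kind: normal, rni: 0.5, cv: 0.10}
    "17-20": {kind: normal, rni: 0.5, cv: 0.10}
    "21-24": {kind: normal, rni: 0.5, cv: 0.10}
  folate_ug:
    "9-12":  {kind: normal, rni: 80,  cv: 0.10}
    "13-16": {kind: normal, rni: 150, cv: 0.10}
    "17-20": {kind: normal, rni: 150, cv: 0.10}
    "21-24": {kind: normal, rni: 150, cv: 0.10}
  vitB12_ug:
    "9-12":  {kind: normal, rni: 0.7, cv: 0.10}
    "13-16": {kind: normal, rni: 0.9, cv: 0.10}
    "17-20": {kind: normal, rni: 0.9, cv: 0.10}
    "21-24": {kind: normal, rni: 0.9, cv: 0.10}
  vitA_ug:
    "9-12":  {kind: normal, rni: 400, cv: 0.20}
    "13-16": {kind: normal, rni: 400, cv: 0.20}
    "17-20": {kind: normal, rni: 400, cv: 0.20}
    "21-24": {kind: normal, rni: 400, cv: 0.20}
  vitC_mg:
    "9-12":  {kind: normal, rni: 30, cv: 0.10}
    "13-16": {kind: normal, rni: 30, cv: 0.10}
    "17-20": {kind: normal, rni: 30, cv: 0.10}
    "21-24": {kind: normal, rni: 30, cv: 0.10}
  vitD_ug:
    "9-12":  {kind: normal, rni: 5, cv: 0.10}
    "13-16": {kind: normal, rni: 5, cv: 0.10}
    "17-20": {kind: normal, rni: 5, cv: 0.10}
    "21-24": {kind: normal, rni: 5, cv: 0.10}
  vitE_mg:
    "9-12":  {kind: ai_threshold, ai: 5}
    "13-16": {kind: normal, rni: 6, cv: 0.10}
    "17-20": {kind: normal, rni: 6, cv: 0.10}
    "21-24": {kind: normal, rni: 6, cv: 0.10}
  calcium_mg:
    "9-12":  {kind: normal, rni: 400, cv: 0.10}
    "13-16": {kind: normal, rni: 500, cv: 0.10}
    "17-20": {kind: normal, rni: 500, cv: 0.10}
    "21-24": {kind: normal, rni: 500, cv: 0.10}
  magnesium_mg:
    "9-12":  {kind: normal, rni: 54, cv: 0.10}
    "13-16": {kind: normal, rni: 60, cv: 0.10}
    "17-20": {kind: normal, rni: 60, cv: 0.10}
    "21-24": {kind: normal, rni: 60, cv: 0.10}
  zinc_mg:
    "9-12":
      high:     {kind: normal, rni: 2.5, cv: 0.125}
      moderate: {kind: normal, rni: 4.1, cv: 0.125}
      low:      {kind: normal, rni: 8.4, cv: 0.125}
    "13-16":
      high:     {kind: normal, rni: 2.4, cv: 0.125}
      moderate: {kind: normal, rni: 4.1, cv: 0.125}
      low:      {kind: normal, rni: 8.3, cv: 0.125}
    "17-20":
      high:     {kind: normal, rni: 2.4, cv: 0.125}
      moderate: {kind: normal, rni: 4.1, cv: 0.125}
      low:      {kind: normal, rni: 8.3, cv: 0.125}
    "21-24":
      high:     {kind: normal, rni: 2.4, cv: 0.125}
      moderate: {kind: normal, rni: 4.1, cv: 0.125}
      low:      {kind: normal, rni: 8.3, cv: 0.125}
  iron_mg:
    "9-12":
      kind: quantile_table
      reference_bioavailability: 0.10
      assumed_bioavailability: 0.05
      quantiles:
        - {percentile: 0.025, intake: 4.33}
        - {percentile: 0.05,  intake: 4.66}
        - {percentile: 0.10,  intake: 5.09}
        - {percentile: 0.25,  intake: 5.88}
        - {percentile: 0.50,  intake: 6.90}
        - {percentile: 0.75,  intake: 8.10}
        - {percentile: 0.90,  intake: 9.36}
        - {percentile: 0.95,  intake: 10.21}
        - {percentile: 0.975, intake: 11.00}
    "13-16": &iron_1_3y
      kind: quantile_table
      reference_bioavailability: 0.18
      assumed_bioavailability: 0.05
      quantiles:
        - {percentile: 0.025, intake: 1.29}
        - {percentile: 0.05,  intake: 1.47}
        - {percentile: 0.10,  intake: 1.72}
        - {percentile: 0.25,  intake: 2.24}
        - {percentile: 0.50,  intake: 3.00}
        - {percentile: 0.75,  intake: 4.02}
        - {percentile: 0.90,  intake: 5.22}
        - {percentile: 0.95,  intake: 6.11}
        - {percentile: 0.975, intake: 7.00}
    "17-20": *iron_1_3y
    "21-24": *iron_1_3y
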