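name: healthy
age_range:
- 20.0
- 65.0
proportion_female: 0.5
male:
  height_mean: 176.0
  height_sd: 7.0
  hw:
    a: 2.213210750399277
    x0: 0.012
    residual_gsd: 1.1
  bmi_target: 24.399999999999999
  hct_mean: 43.039999999999999
  hct_cv: 0.05
female:
  height_mean: 163.0
  height_sd: 6.5
  hw:
    a: 2.178160450787455
    x0: 0.012
    residual_gsd: 1.1
  bmi_target: 23.5
  hct_mean: 38.039999999999999
  hct_cv: 0.05
cyp_abundance_mean:
  CYP1A2: 52.0
  CYP2C9: 73.0
  CYP2C19: 14.0
  CYP2D6: 8.0
  CYP3A4: 137.0
cyp_abundance_cv:
  CYP1A2: 0.4
  CYP2C9: 0.4
  CYP2C19: 0.4
  CYP2D6: 0.4
  CYP3A4: 0.4
albumin_ratio: 1.0
mppgl: 40.0
liver_mass: 1650.0
hepatic_blood_flow: 90.0
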