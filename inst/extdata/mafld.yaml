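name: mafld
age_range:
- 20.0
- 65.0
proportion_female: 0.5
male:
  height_mean: 176.0
  height_sd: 7.0
  hw:
    a: 2.409774663908775
    x0: 0.012
    residual_gsd: 1.1
  bmi_target: 29.699999999999999
  hct_mean: 48.200000000000003
  hct_cv: 0.05
female:
  height_mean: 163.0
  height_sd: 6.5
  hw:
    a: 2.328046731828256
    x0: 0.012
    residual_gsd: 1.1
  bmi_target: 27.300000000000001
  hct_mean: 42.600000000000001
  hct_cv: 0.05
cyp_abundance_mean:
  CYP1A2: 19.239999999999998
  CYP2C9: 52.559999999999995
  CYP2C19: 4.298
  CYP2D6: 5.848
  CYP3A4: 85.350999999999999
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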