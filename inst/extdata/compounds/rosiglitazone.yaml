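name: rosiglitazone
dose_mg: 4.0
ka: 1.8
fa_fg: 0.99
fu: 0.002
bp_ratio: 0.8
bp_ref_hct: 45.0
vss: 0.25
clint_per_pmol:
  CYP1A2: 0.0
  CYP2C9: 2.054794520547945
  CYP2C19: 0.0
  CYP2D6: 0.0
  CYP3A4: 0.0
clint_other: 150.0
cl_renal: 0.0
fm_cyp:
  CYP2C9: 0.5
mm: ~
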