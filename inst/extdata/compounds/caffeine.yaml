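name: caffeine
dose_mg: 150.0
ka: 3.0
fa_fg: 1.0
fu: 0.7
bp_ratio: 1.04
bp_ref_hct: 45.0
vss: 0.5
clint_per_pmol:
  CYP1A2: 0.036538461538462
  CYP2C9: 0.0
  CYP2C19: 0.0
  CYP2D6: 0.0
  CYP3A4: 0.0
clint_other: 0.1
cl_renal: 0.0
fm_cyp:
  CYP1A2: 0.95
mm: ~
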