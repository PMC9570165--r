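name: s-warfarin
dose_mg: 10.0
ka: 1.0
fa_fg: 1.0
fu: 0.01
bp_ratio: 0.55
bp_ref_hct: 45.0
vss: 0.14
clint_per_pmol:
  CYP1A2: 0.0
  CYP2C9: 0.034520547945205
  CYP2C19: 0.0
  CYP2D6: 0.0
  CYP3A4: 0.0
clint_other: 0.28
cl_renal: 0.0
fm_cyp:
  CYP2C9: 0.9
mm: ~
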