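name: midazolam
dose_mg: 5.0
ka: 3.0
fa_fg: 0.55
fu: 0.02
bp_ratio: 0.66
bp_ref_hct: 45.0
vss: 1.1
clint_per_pmol:
  CYP1A2: 0.0
  CYP2C9: 0.0
  CYP2C19: 0.0
  CYP2D6: 0.0
  CYP3A4: 1.98978102189781
clint_other: 17.400000000000016
cl_renal: 0.0
fm_cyp:
  CYP3A4: 0.94
mm: ~
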