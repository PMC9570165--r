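name: metoprolol
dose_mg: 100.0
ka: 2.5
fa_fg: 0.95
fu: 0.88
bp_ratio: 1.15
bp_ref_hct: 45.0
vss: 4.2
clint_per_pmol:
  CYP1A2: 0.0
  CYP2C9: 0.0
  CYP2C19: 0.0
  CYP2D6: 6.0
  CYP3A4: 0.0
clint_other: 11.999999999999996
cl_renal: 0.0
fm_cyp:
  CYP2D6: 0.8
mm: ~
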