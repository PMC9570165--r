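name: dextromethorphan
dose_mg: 30.0
ka: 1.5
fa_fg: 0.9
fu: 0.35
bp_ratio: 1.0
bp_ref_hct: 45.0
vss: 6.0
clint_per_pmol:
  CYP1A2: 0.0
  CYP2C9: 0.0
  CYP2C19: 0.0
  CYP2D6: 9.0
  CYP3A4: 0.029197080291971
clint_other: 3.999999999999995
cl_renal: 0.0
fm_cyp:
  CYP2D6: 0.9
  CYP3A4: 0.05
mm: ~
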