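name: omeprazole
dose_mg: 20.0
ka: 2.0
fa_fg: 0.9
fu: 0.045
bp_ratio: 0.6
bp_ref_hct: 45.0
vss: 0.3
clint_per_pmol:
  CYP1A2: 0.0
  CYP2C9: 0.0
  CYP2C19: 9.321428571428571
  CYP2D6: 0.0
  CYP3A4: 0.109489051094891
clint_other: 4.500000000000004
cl_renal: 0.0
fm_cyp:
  CYP2C19: 0.87
  CYP3A4: 0.1
mm: ~
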