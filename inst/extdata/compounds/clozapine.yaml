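name: clozapine
dose_mg: 12.5
ka: 1.5
fa_fg: 0.9
fu: 0.05
bp_ratio: 0.85
bp_ref_hct: 45.0
vss: 5.0
clint_per_pmol:
  CYP1A2: 2.557692307692307
  CYP2C9: 0.0
  CYP2C19: 0.0
  CYP2D6: 0.0
  CYP3A4: 0.346715328467153
clint_other: 9.500000000000009
cl_renal: 0.0
fm_cyp:
  CYP1A2: 0.7
  CYP3A4: 0.25
mm: ~
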