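"compound","enzyme","regimen","metric","healthy","mafld","printed_ratio"
"caffeine","CYP1A2","single","cmax",3399,3885,1.14
"caffeine","CYP1A2","single","auc",23712,50331,2.12
"caffeine","CYP1A2","multiple","cmax",3597,5568,1.55
"caffeine","CYP1A2","multiple","auc",25130,72715,2.89
"clozapine","CYP1A2","single","cmax",54.4,62.6,1.15
"clozapine","CYP1A2","single","auc",436,788,1.81
"clozapine","CYP1A2","multiple","cmax",58.4,81.3,1.39
"clozapine","CYP1A2","multiple","auc",469,1026,2.19
"s-warfarin","CYP2C9","single","cmax",924,866,0.94
"s-warfarin","CYP2C9","single","auc",15458,15500,1
"s-warfarin","CYP2C9","multiple","cmax",1877,1983,1.06
"s-warfarin","CYP2C9","multiple","auc",31630,35778,1.13
"rosiglitazone","CYP2C9","single","cmax",245,241,0.98
"rosiglitazone","CYP2C9","single","auc",1152,1331,1.16
"rosiglitazone","CYP2C9","multiple","cmax",248,247,0.99
"rosiglitazone","CYP2C9","multiple","auc",1166,1364,1.17
"omeprazole","CYP2C19","single","cmax",153,236,1.54
"omeprazole","CYP2C19","single","auc",467,1174,2.52
"omeprazole","CYP2C19","multiple","cmax",191,323,1.7
"omeprazole","CYP2C19","multiple","auc",666,2112,3.17
"dextromethorphan","CYP2D6","single","cmax",4.25,5.08,1.2
"dextromethorphan","CYP2D6","single","auc",49.9,66,1.32
"dextromethorphan","CYP2D6","multiple","cmax",7.56,10.1,1.33
"dextromethorphan","CYP2D6","multiple","auc",63.6,89.8,1.41
"metoprolol","CYP2D6","single","cmax",NA,172,1.22
"metoprolol","CYP2D6","single","auc",841,1223,1.45
"metoprolol","CYP2D6","multiple","cmax",145,180,1.24
"metoprolol","CYP2D6","multiple","auc",863,1276,1.48
"midazolam","CYP3A4","single","cmax",18.7,20.7,1.11
"midazolam","CYP3A4","single","auc",54.7,84.8,1.55
"midazolam","CYP3A4","multiple","cmax",19.9,23.4,1.18
"midazolam","CYP3A4","multiple","auc",56.1,89.7,1.6
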