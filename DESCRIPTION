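Package: mafldpbpk
Title: Virtual MAFLD Population Pharmacokinetic Simulation and Validation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Constructs a virtual population reflecting the physiological and
    CYP-enzyme changes reported in metabolic-associated fatty liver disease
    (MAFLD), pools study-level MAFLD/control ratios of CYP abundance and
    activity, simulates oral probe-substrate pharmacokinetics with a
    well-stirred hepatic clearance model scaled from per-CYP abundances
    (IVIVE), runs virtual clinical trials comparing MAFLD and healthy
    populations by geometric-mean exposure ratios, and validates simulated
    ratios against in vitro and animal comparators by mean fold error.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    deSolve,
    pracma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
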