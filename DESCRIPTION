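Package: phsolv
Title: Solubility-pH Speciation, Salt Solubility Products, Aggregation
    and CMC Analysis for Ionizable Drugs
Version: 0.1.0
Authors@R:
    person("phsolv", "developers", email = "phsolv@example.org",
           role = c("aut", "cre"))
Description: Equilibrium analysis of solubility-pH profiles of ionizable
    drugs in multi-counterion media. Provides a multi-species, multi-solid
    speciation solver with automatic ionic-strength compensation (Davies
    activity model plus a salting-out term for the neutral species),
    conversion between operational pH readings and concentration-scale pcH,
    weighted nonlinear least-squares refinement of intrinsic solubility,
    salt solubility products and self-aggregation constants from log S-pH
    titration data, critical micelle concentration estimation from
    conductometric titrations by segmented regression, elemental-composition
    assignment of salt/base hydrates, and a synthetic-data generator for
    pH-ramp shake-flask designs. Ships a default model for imipramine and
    its hydrochloride and phosphate salts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
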