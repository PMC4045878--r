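Package: pduflux
Title: Metabolic Flux Analysis of the Lactobacillus reuteri Pdu Pathway
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Stoichiometric modelling and metabolic flux analysis of glycerol
    biotransformation by resting cells of Lactobacillus reuteri through the
    propanediol-utilization (Pdu) pathway. Provides the pathway network
    (glycerol to 3-hydroxypropionaldehyde, then to 1,3-propanediol and
    3-hydroxypropionic acid with NADH/NAD+ coupling), the batch and
    variable-volume fed-batch mass-balance rate equations, a kinetic
    bioreactor simulator of resting-cell biotransformation protocols
    (multi-step fed-batch and batch with a carbohydrazide aldehyde
    scavenger), per-feed-step flux estimation from concentration time
    series, and a synthetic-data generator with an HPLC-like measurement
    noise model.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    deSolve,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    withr,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
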