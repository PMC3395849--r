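Package: silabel
Title: In Silico Labeling for Time-Dependent Half-Life and Transit-Time
    Analysis of Reaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes time-dependent species half-lives, label half-lives
    and label transit-times for ODE reaction-network models by in silico
    labeling: the network is automatically extended with labeled and free
    counterparts of tracked species, honoring combinatorial multiplicity
    of complexes and ordered reactant lists, prohibiting double-counting
    of cycling label, and excluding upstream fluxes. Includes least-squares
    model calibration and profile-likelihood confidence envelopes for the
    label characteristics, plus a JAK-STAT nucleocytoplasmic shuttling
    model with a synthetic-data generator for end-to-end analyses.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
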