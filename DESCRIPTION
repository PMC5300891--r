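Package: zipkinetics
Title: Kinetic Modelling of Bivalent ZBP1 KH3-KH4 Binding to the beta-Actin Zipcode RNA
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mass-action kinetic model of the bivalent interaction between the
    KH3-KH4 di-domain of ZBP1 (IMP1/IGF2BP1) and the bipartite beta-actin
    Zipcode RNA. The six-species reaction network couples two single-domain
    binding events through a ring-closure (RNA looping) step and a competing
    2:1 protein:RNA pathway. Provides derivation of the closure rates from
    measured single-domain kinetics and the di-domain dissociation constant,
    fixed-step fourth-order Runge-Kutta time-course simulation with a clamped
    dissociation-phase protocol, direct and detailed-balance steady-state
    solvers with apparent-Kd and fraction-bound summaries, concentration and
    closing-rate sweeps, a biolayer interferometry (BLI) kinetic-fitting
    pipeline (kobs, kon, Kd, koff), and a seeded synthetic sensorgram
    generator for parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    minpack.lm,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
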