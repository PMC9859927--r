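Package: vaxalloc
Title: Optimal Vaccine Allocation in Multi-Group SIR Epidemic Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying targeted vaccination in multi-group
    susceptible-infected-recovered (SIR) epidemics with imperfect vaccines.
    Implements a 6n-compartment model in which doses are distributed at
    random among the not-yet-vaccinated members of each group, simulates it
    under piecewise-constant rate- and supply-constrained vaccination
    policies, and evaluates a weighted final-size objective. Two asymptotic
    policy constructions are provided: a vulnerable-group-first policy swap
    that redirects an arbitrary policy's early doses to a small vulnerable
    group, and a small-supply linearization of the final-size equations that
    reduces optimal allocation to a knapsack problem solved by a per-dose
    marginal-cost gradient. Includes next-generation-matrix calibration from
    age-structured contact matrices, a synthetic assortative contact-matrix
    generator, worked two-group, homogeneous and age-structured examples,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
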