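Package: vaxsched
Title: Optimization of Cancer Vaccination Schedules with a Genetic
    Algorithm and an Agent-Based Tumor-Immune Simulator
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Searches the constrained binary space of vaccine
    administration schedules for protocols that protect a cohort of
    simulated ("virtual") mice with as few administrations as possible.
    A seeded lattice agent-based model of vaccine-elicited immune
    response versus continuous mammary carcinogenesis acts as the
    fitness evaluator inside a master-slave genetic algorithm.  Includes
    schedule encoding and admissibility accounting, the simulator, a
    cohort-level fitness, constraint-preserving genetic operators,
    pluggable evaluation backends (serial, multicore, scripted) with a
    bit-reproducibility contract, and an analytic cost model for the
    per-generation runtime of master-slave parallel evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    parallel,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
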