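Package: ontosel
Title: Directional and Disruptive Selection on Traits Shaping Ontogeny in
    Class-Structured Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Invasion analysis for non-plastic quantitative traits that govern
    the development of internal states (e.g. body size) in age- and
    class-structured populations. Builds the mutant next-generation matrix and
    basic reproductive number from user-declared class-oriented fecundity,
    mortality and developmental rates, solves the associated costate
    (reproductive-value) differential equations, and returns age-resolved
    directional and quadratic selection coefficients, singular strategies,
    convergence-stability (Jacobian) and uninvadability (Hessian)
    classifications. Ships a worked two-sex model of growth under size-matching
    sexual selection with diploid, haplodiploid and genetically constrained
    (shared-trait) variants, and a stochastic individual-based simulator used
    to confirm convergence and evolutionary branching predictions.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
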