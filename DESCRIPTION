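Package: polysweep
Title: Architectures of Polygenic Adaptation for Redundant Traits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Forward simulation and analytical theory for the adaptive
    architecture of a redundant binary trait (such as pathogen resistance)
    governed by L fully or partially redundant loci. Provides a
    Wright-Fisher simulator under linkage equilibrium with
    mutation-selection-drift burn-in and a fitness-based stopping rule, a
    Yule pure-birth model of the stochastic establishment phase together
    with its inverted-Dirichlet limit law, deterministic selection dynamics
    with frequency-ratio invariance, closed-form joint and marginal
    distributions of stopped allele frequencies, and a classification of
    adaptive regimes (completed sweeps, partial sweeps, frequency shifts)
    by the population-scaled background mutation rate.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    deSolve,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pracma
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'modelParams.R'
    'analytics.R'
    'yule.R'
    'wrightFisher.R'
    'deterministic.R'
    'summaries.R'
    'io.R'
    'polysweep-package.R'
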