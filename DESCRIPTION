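Package: signalurn
Title: Exemplar Urn-Model Simulations of Emergent Signaling Conventions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Agent-based simulations of the emergence of learned signaling
    conventions in populations of exemplar ("urn") learners. Implements
    Roth-Erev reinforcement, Yes/No and Referential feedback (Naming Game),
    and observational/obverter learning regimes on a common exemplar store,
    together with lateral inhibition, punishment, memory limits, closed and
    gradual-replacement population dynamics, communicative-accuracy metrics,
    named replication presets, and batch Monte-Carlo drivers for convergence,
    scaling, and Zipf-distributed meaning-frequency studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    igraph,
    graphics,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
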