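Package: dhfret
Title: Kinetics of Mcm2-7 Double-Hexamer Formation from Single-Molecule FRET Traces
Version: 0.1.0
Authors@R:
    person("Sam", "Ortiz", email = "sortiz@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for colocalization single-molecule FRET (smFRET)
    recordings of eukaryotic replicative-helicase loading. Converts
    donor/acceptor intensity traces for DNA-colocalized spots into
    time-zero-aligned FRET-efficiency records, builds time-evolved E_FRET
    density histograms with constrained two-Gaussian mixture fits, fits a
    generalized three-state kinetic model to the pooled records by
    empirical-Bayes variational hidden-Markov inference, decodes per-molecule
    state paths, and reports rate constants, initial state fractions,
    rastergrams and cohort dwell statistics. Includes a continuous-time
    Markov-chain trace simulator with full ground truth so the whole pipeline
    is testable without archived experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    optparse,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
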