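Package: bulbnet
Title: Anatomically Grounded Olfactory Bulb Network Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Builds large-scale mitral-cell/granule-cell networks of the
    olfactory bulb from dendritic density distributions. Connection
    probabilities between mitral and granule cells are derived from the
    geometric overlap of a radially symmetric lateral-dendrite density on a
    disk with a conical spine-density field, and networks are wired
    sequentially under per-cell spine budgets. Cells are simulated as
    Izhikevich dynamical systems coupled through dendrodendritic AMPA, NMDA
    and GABA receptors, with Poisson sensory drive, local field potential
    synthesis and spectral analysis, and protocols for lateral inhibition,
    odor-pattern decorrelation, cortical feedback and granule-cell
    neurogenesis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    jsonlite,
    minpack.lm,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
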