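Package: fluxmed
Title: Two-Stage Flux Balance Analysis for Drug-Target Identification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constraint-based identification of candidate drug targets in
    metabolic networks. Extends classic flux balance analysis with explicit
    metabolite mass-flow variables and solves two linear programs: a
    pathologic-state program that maximizes weighted mass flows of biomass
    metabolites, and a medication-state program that forces disease-causing
    metabolites into clinically healthy mass-flow ranges while minimizing the
    summed deviation (side effect) of all other metabolites from theirs.
    Reactions whose flux changes between the two states form a subnetwork
    whose source reactions - those left without reactants after pruning
    unproduced compounds - are reported as drug targets, with the flux change
    as a dose proxy. Includes parsers for reaction-equation text and TSV/YAML
    model files, a reproducible layered random-network generator for
    validation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
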