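Package: sdasnet
Title: Seed-Dependent Autocatalytic Systems in Chemical Reaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting and analysing seed-dependent autocatalytic
    systems (SDASs) in stoichiometric reaction networks. Given a database of
    unidirectional reactions and a set of ultimate food species, the package
    computes food closures by catalyst-aware network expansion, certifies
    seed-induced autocatalytic subnetworks by linear-programming feasibility
    over the partitioned stoichiometric matrix, enumerates minimum-cardinality
    autocatalytic motifs by integer programming, classifies seeds (supported,
    unsupported, singleton, composite) and cliques, organises SDASs into
    trophic tiers, and analyses inter-SDAS ecology (competition, predation,
    mutualism) and scaffolding by reaction-removal ablation. Includes readers
    and writers for tabular and plain-text reaction formats, embedded toy
    networks, and a generator of synthetic tiered networks with planted
    autocatalytic cycles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    readxl,
    optparse
Config/testthat/edition: 3
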