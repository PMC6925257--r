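Package: satdyn
Title: Multilevel Stochastic Simulation of Satellite Plasmid Evolution
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how nonautonomous satellite plasmids arise from
    multicopy IncQ-family plasmids. Implements a two-level stochastic simulator of
    plasmid replication and random segregation inside dividing bacterial cells
    competing under serial-dilution regimes (equilibrium tuning of realized
    fitness, phenotypic-delay trajectories of new mutant plasmids, and
    establishment probabilities under daily transfer bottlenecks); enumeration of
    short near-perfect direct repeats (microhomologies) on circular plasmid
    sequences that can mediate deletions; combinatorics of deletion endpoints on
    annotated circular plasmid maps classifying satellite-forming versus
    accessory-gene deletions; and generators for synthetic plasmid sequences,
    maps, and simulation presets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Software, Genetics, Evolution, Sequencing
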