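Package: pathcontext
Title: Metabolic Pathway Reaction Networks in Context with Flux Balance Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study a focal metabolic pathway both in isolation and in the
    context of the pathways connected to it. Builds directed reaction networks from
    KGML or tabular pathway definitions, detects connected pathways through shared
    metabolites, assembles per-addition combined networks and the combined connected
    network, and computes degree, clustering, closeness and betweenness together with
    top-percentile hub detection and cross-organism variation statistics. A flux
    balance analysis core reads stoichiometric models from SBML, solves two-stage
    (parsimonious) flux optimisation, and scans gene and reaction deletions and
    fractional-efficiency constraints for their effect on flux through annotated
    pathway sections. Hub sets and essentiality scans are compared through overlap
    reports and rank-based statistics, and a synthetic-data module generates pathway
    ensembles and toy stoichiometric models with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    xml2,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
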