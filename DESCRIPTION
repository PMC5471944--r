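Package: evinet
Title: Evidence Networks Linking Drugs to Mediator Genes via STITCH/STRING-Style Interaction Graphs
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constructs evidence networks: small sub-networks of a
    STITCH/STRING-style chemical-protein interaction graph that connect a
    drug to a mediator gene through the best-evidenced paths. Edges carry
    per-channel evidence scores (experimental, database, textmining, ...)
    combined into a confidence S in [0,1]; paths are ranked by the weight
    w = 1 - S per edge and enumerated with a modified Yen's K-shortest-paths
    algorithm under a distinct-node stopping rule. Includes drug-mediator
    pair classification by intermediate-gene count, channel re-weighting,
    single-source networks (k closest drugs to a mediator), pathway-weighted
    networks merging differential-dependency-network neighbors with
    master-graph edge induction, condition-specific networks, InChIKey-based
    chemical matching, STRING/STITCH flat-file parsing and writing, a
    synthetic fixture generator, and Cytoscape.js JSON / GraphML export.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, jsonlite, xml2
Suggests: testthat (>= 3.0.0), igraph, optparse
SystemRequirements: Open Babel (obabel on PATH) for the chemical
    identifier module; all graph functionality works without it.
biocViews: Network, GraphAndNetwork, Pathways, SystemsBiology
Config/testthat/edition: 3
RoxygenNote: 7.3.3
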