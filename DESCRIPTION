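Package: ligandkit
Title: Small-Molecule Analysis for Macromolecular Structures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A desk-scale toolkit for analysing small molecules bound to
    macromolecular structures: chemical-component parsing and sanitization,
    descriptors, Murcko scaffolds and rule-based fragmentation, PARITY
    maximum-common-substructure similarity, inference of covalently linked
    multi-component bound molecules (CLCs) with InChIKey-keyed identifier
    assignment, geometric protein-ligand contact typing in four categories,
    functional-role classification of ligands (cofactor-like, reactant-like,
    drug-like), per-atom interaction-frequency aggregation, and ligand
    quality flagging. Ships a deterministic synthetic fixture generator so
    the whole pipeline is testable without downloading archive entries.
License: MIT
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), optparse, ChemmineR
SystemRequirements: OpenBabel (obabel on PATH, for SMILES/InChI/InChIKey
    generation)
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
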