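Package: pdzome
Title: Genome-Wide Prediction and Analysis of PDZ Domain Binding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for genome-wide prediction of PDZ domain interactions
    with protein C-termini. Scores 18-residue PDZ binding pockets against
    5-residue C-terminal ligands with an additive pairwise lookup-table
    (psi) model, calls binders at a fixed threshold, and provides the
    downstream analyses used in PDZome studies: cross-reactivity
    statistics, hierarchical clustering of binding-score profiles into
    ligand-specific and promiscuous groups, binding-pocket residue
    enrichment, in-silico alphaB1/alphaB5 mutation scans, position weight
    matrices of predicted ligands, interactome degree and Gene Ontology
    compartment context, and multi-species PDZome catalog summaries. A
    seedable synthetic-data module emulates every pipeline input with
    planted structure for parameter-recovery benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    stats,
    utils,
    withr
Suggests:
    mclust,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
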