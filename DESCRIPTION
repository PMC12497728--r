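Package: ClonalKinetics
Title: Longitudinal B-Cell Receptor Repertoire Analysis and Clonal
    Lineage Expansion Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for longitudinal antibody (B-cell receptor) repertoire
    analysis in AIRR-style rearrangement tables: clonal lineage clustering by
    CDR3 amino-acid hamming distance within V/J groups, repertoire diversity
    (Shannon, Gini, top-N cumulative frequency), Morisita-Horn and overlap
    similarity, somatic hypermutation rate and mutation-class partitioning,
    log2 fold-change classification of lineage dynamics across timepoints,
    multi-criteria expanded-lineage identification with matched control
    sampling, origin tracing of expanded lineages, and Neighbor-Joining
    lineage phylogenies. Includes a seeded synthetic longitudinal cohort
    generator with planted clonal expansions and ground truth, so the whole
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    data.table,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    phangorn
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
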