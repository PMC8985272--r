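Package: pangraphr
Title: Synteny-Aware Bacterial Pangenome Graph Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds per-strain synteny graphs and a weighted pangenome graph
    from annotated bacterial genomes (GFF3 annotations plus predicted protein
    sequences). Proteins are clustered with an iterative descending-identity
    cascade, paralogous clusters are split into neighbourhood-specific
    subclusters, and clusters are partitioned into hard core, soft core,
    shell and cloud by genome occupancy. Finished template genomes can be
    used to assign clusters to replicons (chromosomes or plasmids), and five
    classes of structural pattern (orphans, uniques, variants, insertions
    and InDel cycles) are detected on the pangenome graph. Graphs are
    exchanged as GraphML for visualisation in tools such as Cytoscape, with
    highlighting overlays for strain groups and clade-specific gene sets.
    A seeded synthetic-cohort generator with a ground-truth manifest
    supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    Biostrings,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
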