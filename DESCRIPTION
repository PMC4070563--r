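Package: ternet
Title: Ternary Co-Expression Network Inference and Promoter Element Discovery
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds gene co-expression networks from ternary
    differential-expression profiles (up / down / no-change calls across
    many experimental conditions) using both linear association (Pearson
    correlation with fixed-threshold and mutual k-nearest-neighbour edge
    rules) and non-linear association (Kraskov k-nearest-neighbour mutual
    information with ARACNE, CLR and MRNET post-processing and
    max-fraction thresholding).  Provides a full topological
    characterisation battery (degree distributions and power-law fits,
    clustering coefficients, path metrics, betweenness and closeness
    centralities, shared-neighbour statistics, connected components, hub
    extraction), module detection by edge-clustering-coefficient
    agglomeration (FAG-EC) and Markov clustering (MCL), and a
    genome-scale cis-regulatory element discovery engine: seed-and-extend
    ungapped local alignment over promoter sets with Karlin-Altschul
    E-values, shared 6-mer candidate extraction, and POBO-style bootstrap
    enrichment with fold-ratio tiers and precision evaluation against
    known elements.  Includes seeded generators for synthetic expression
    matrices with planted co-expressed modules and promoter sets with
    planted elements.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    igraph,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'datasets.R'
    'synthetic.R'
    'linear-net.R'
    'mi-net.R'
    'topology.R'
    'module-detect.R'
    'align.R'
    'enrichment.R'
    'pipeline.R'
    'ternet-package.R'
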