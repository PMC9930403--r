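Package: synteks
Title: Synteny, Ks-Based Duplication Dating, and Genome Content Analysis
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Molecular-evolution and genome-content analyses for large,
    repeat-rich plant genomes such as hop (Humulus lupulus) and hemp
    (Cannabis sativa). Estimates per-pair synonymous substitution rates (Ks)
    with the Nei-Gojobori (1986) counting method, fits finite Gaussian
    mixtures to log-transformed Ks distributions by EM with ICL model
    selection to date whole-genome duplication and speciation peaks
    (T = Ks/2*lambda), detects and summarises collinear syntenic blocks
    (MCScanX-style), tests feature-class co-occurrence in blocks and GO-style
    term enrichment with hypergeometric tests and Benjamini-Hochberg FDR,
    merges and filters gene-model sets from two annotation sources, profiles
    assembly composition and k-mer based genome size and heterozygosity, and
    scans bi-parental mapping populations for sex-associated markers to
    nominate a putative sex chromosome. A full set of synthetic-data
    generators with known ground truth exercises every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    mclust,
    seqinr,
    jsonlite
Config/testthat/edition: 3
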