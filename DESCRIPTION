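Package: lbdfam
Title: Genome-Wide Characterization of LOB-Domain (LBD) Transcription Factor Gene Families
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to characterize the plant-specific LATERAL ORGAN BOUNDARIES
    Domain (LBD) transcription-factor gene family in a sequenced genome, as
    applied to grapevine (Vitis vinifera). Implements a motif-grammar scanner
    for the three LOB-domain blocks (CX2CX6CX3C zinc-finger-like C-block, GAS
    block, LX6LX3LX6L leucine-zipper-like motif) with Class I/II calls; gene
    catalog statistics, nomenclature parsing and tandem-duplication detection;
    neighbor-joining phylogenies with bootstrap supports, branch collapsing and
    bootstrap-thresholded subclass assignment against reference genes;
    reciprocal-best-hit orthology with retention filters and Nei-Gojobori
    (1986) Ka/Ks; promoter extraction with no-ORF truncation, IUPAC
    cis-element scanning, hypergeometric enrichment and enumerative k-mer
    discovery; expression-atlas tissue assignment and co-expression clustering
    at a Pearson-distance cut. A seeded synthetic-data generator produces every
    input type with known ground truth so each stage has a planted-signal
    recovery test.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    SummarizedExperiment,
    rtracklayer,
    ape,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
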