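Package: tlpminer
Title: Genome-Wide Mining and Characterization of Thaumatin-Like Protein Gene Families
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Signature-based identification and characterization of
    thaumatin-like protein (TLP, pathogenesis-related family 5) genes in
    cereal genomes. Implements a PROSITE-style pattern engine for the
    thaumatin family signature, a candidate-selection funnel (homology-hit
    e-value filter, signature verification, collapse to the longest isoform
    per locus), ProtParam-convention physicochemical characterization
    (isoelectric point by Bjellqvist pKa bisection, average-mass molecular
    weight, cysteine census, carbohydrate-binding-motif detection), GFF3
    driven exon/intron structure classification and chromosome distribution,
    neighbor-joining phylogeny with column-resampling bootstrap over protein
    alignments, FPKM expression profiling with average-linkage clustering and
    RT-PCR band quantification, and seeded synthetic-data generators
    (proteomes, genomes, alignments evolved on known trees, expression
    matrices) providing ground truth for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    Biostrings,
    GenomicRanges,
    IRanges,
    methods,
    rtracklayer,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
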