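Package: sparseMethylome
Title: Analysis of Sparsely Methylated Genomes from Bisulfite CpG Calls
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing genomes in which only a small minority of
    CpG dinucleotides carry 5-methyl-cytosine, as found in cephalopods and
    many other invertebrates. Reads per-cytosine methylation calls (CGmap
    and Bismark coverage dialects), classifies CpGs by methylation level,
    annotates them against gene models and RepeatMasker repeats, builds
    scaled-bin winsorized-mean metaplots and flanked per-transcript
    matrices, discovers gene-body methylation patterns by one-dimensional
    k-means, and couples the patterns to tissue expression (percentile
    curves, Kruskal-Wallis with Dunn post-hoc, z-score expression
    clustering, hypergeometric GO over-representation). Ships a synthetic
    methylome generator with ground truth so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
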