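Package: patseqr
Title: Genome-Wide Alternative Polyadenylation Analysis from Poly(A)-Tag Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for genome-wide analysis of alternative polyadenylation
    (APA) from mapped poly(A)-tag (PAT) sequencing data. Reduces mapped tags
    to single-nucleotide cleavage coordinates, filters likely internal-priming
    artifacts at genomic A-tracts, builds poly(A) sites (PAS) and 24-nt
    poly(A)-site clusters (PAC) with dataset-level count thresholds, assigns
    clusters to genes and genomic regions using 3'UTR-extended annotations,
    computes tissue-wise relative PAC usage, differential-usage calls with
    FDR control, single-nucleotide composition profiles around cleavage sites
    (including N6A8 internal-priming controls), and PAT-based gene expression
    with quantile normalization. Includes a synthetic genome/tag simulator
    with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    data.table,
    jsonlite,
    yaml,
    graphics,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    limma
Config/testthat/edition: 3
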