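Package: edcscan
Title: Discovery and Characterization of Epidermal Differentiation Complex Genes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Annotates epidermal differentiation complex (EDC) loci in genomic
    sequence. Locates the S100A anchor genes that border the cluster, finds
    S100-fused-type-protein (SFTP) genes by six-frame translated homology
    search with the 400-nucleotide coding-extension rule, discovers
    single-coding-exon EDC (SEDC) genes by composition-biased open reading
    frame scanning with a splice-acceptor requirement, validates gene models
    with exon-spanning RNA-seq reads, TATA boxes and canonical GT-AG introns,
    quantifies tissue-restricted expression by perfect-identity translated
    read counting, and profiles the amino-acid composition, repeats and
    sequence logos of the encoded proteins. A synthetic-locus simulator with
    ground-truth annotations allows the whole analysis to run self-contained.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
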