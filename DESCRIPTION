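Package: homeoconverge
Title: Genomic and Epigenomic Convergence Analysis for Allopolyploid Homoeologs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative analysis of promoter sequence and epigenome
    conservation between an allotetraploid's subgenomes and its two diploid
    progenitors. Identifies 1:1:1:1 homoeologous gene tetrads by reciprocal
    best hits filtered for collinearity, aligns homoeologous promoters with a
    deterministic global affine-gap aligner, projects histone-mark and
    accessible-chromatin peaks across genomes, classifies homoeolog pairs by
    dual sequence/epigenome conservation (Class I/II/III), categorises
    intersubgenomic convergence (Same/Convergent/Others), scores
    transcription-factor binding-site conservation from position weight
    matrices, classifies promoter variants (SNV/InDel/SV), and computes the
    accompanying expression-divergence statistics. Includes a synthetic
    four-genome benchmark generator with known truth labels for every layer.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    rtracklayer,
    GenomicRanges,
    stats,
    tools,
    utils,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
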