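Package: hicontext
Title: Genetic-Context Classification of HicA Toxin-Domain Loci
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Classifies genes encoding HicA toxin domains into fourteen
    genetic-context classes from genome annotations. Reads GenBank or
    GFF3+FASTA annotations, assigns protein domain architectures by scanning
    against position-specific scoring profiles (or ingesting HMMER domtblout
    tables), extracts gene neighborhoods with intergenic gaps and strand
    relationships, applies a rule engine covering bicistronic hicAB/hicBA
    operons, prokaryotic-Viperin-adjacent loci, fused monocistronic toxins and
    SMC-HicA fusions, screens small HicB antitoxins for pseudogene candidates,
    and summarizes per-class statistics. Includes a neighbor-joining phylogeny
    of toxin domains with a class-purity statistic, rigid-body superposition
    of CA coordinate sets with iterative pair pruning, and a synthetic
    annotation generator that produces ground-truth-labelled genomes for all
    fourteen configurations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    S4Vectors,
    BiocGenerics,
    rtracklayer,
    ape,
    bio3d,
    jsonlite,
    yaml,
    withr,
    Rcpp,
    stats,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
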