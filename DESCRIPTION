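Package: pansynt
Title: Synteny-Anchored Variant Discovery and Pan-Genome Analysis for De
    Novo Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds pairwise synteny blocks between de novo genome
    assemblies and a reference genome via unique k-mer anchoring,
    score-maximising chaining and single-coverage netting; calls SNPs,
    short indels and structural variants (large insertions and deletions,
    copy-number gains and losses, translocations) anchored in clean
    synteny blocks; merges per-accession call sets into a multi-sample
    genotype matrix with reference-genotype imputation; extracts novel
    sequence, builds pan-/core-genome size curves and fits an asymptotic
    regression model; computes nucleotide diversity (theta-pi, Watterson's
    theta-w), SNP functional effects, ortholog groups and gene-family
    copy-number statistics; and validates SV breakpoints with long reads.
    A synthetic-genome module simulates a reference with clustered gene
    families and TE-like repeats, derives accession genomes by planting
    known variants, fragments them into gapped scaffolds and simulates
    long reads, providing an exact truth set for end-to-end benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    Rcpp,
    minpack.lm,
    stats,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    seqinr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
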