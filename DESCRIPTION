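Package: hetsnp
Title: SNP Discovery, Filtering and Validation for Highly Heterozygous
    Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for mining single nucleotide polymorphisms from
    quality-annotated EST contig alignments of highly heterozygous,
    multi-species plant genomes and for carrying the candidates through
    to a validated genotyping panel. Implements a Bayesian two-hypothesis
    polymorphism posterior over aligned base calls, neighbourhood-quality
    (SNP block) tagging, a sequential in-silico filter cascade on read
    depth, minor allele frequency, taxon representation, repeat-free and
    SNP-free flanking sequence and exon context, GoldenGate-style assay
    quality statistics (call rate, GenCall50, assayed MAF, conversion
    rate, cross-species transferability), trio-based Mendelian
    transmission checks, and exact-binomial sequence-based genotype
    validation. A synthetic-data module simulates multi-species diploid
    haplotypes, quality-dependent EST reads, genotype panels, trios and
    shotgun allele counts so that every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    jsonlite,
    rtracklayer,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
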