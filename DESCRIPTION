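Package: passageStability
Title: Genomic Stability of Cell-Culture Passages from Multi-Sample Variant Callsets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to assess the genomic stability of cultured cell lines
    across serial passages from a jointly genotyped multi-sample SNP callset.
    Implements GATK-style hard-site filters and cohort-level depth, minor
    allele frequency and missingness filters; partitions sites into
    cross-sample fixed versus variable; detects per-sample private genotypes;
    builds a per-passage summary table (median depth and genotype quality,
    non-fixed and private site counts, differences versus the primary-tissue
    sample); and compares depth and genotype quality of private sites against
    all other sites with a Mann-Whitney rank-sum test (exact enumeration for
    small groups, tie-corrected normal approximation otherwise). Companion
    genome metrics cover Phred quality/error conversion, heterozygosity
    density, assembly contiguity statistics (N50/L50/N90/L90, GC), macro-
    versus microchromosome classification at a configurable length cutoff and
    per-class gene and intron summaries from GFF3 annotation. A seeded
    simulator generates diploid founder/passage callsets with replicate
    lineages, novel mutations, depth and quality noise and low-quality
    artifact calls, together with complete truth tables, so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    vcfR,
    data.table,
    stats,
    utils,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
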