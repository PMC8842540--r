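Package: rdnaepi
Title: Haplotype Structure and Allele-Specific Methylation of Ribosomal DNA
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing the genetic and epigenetic architecture of
    multi-copy 45S ribosomal DNA (rDNA). From long-read unit observations it
    discovers and assigns rDNA haplotypes, computes within-read haplotype
    co-localization and per-haplotype CpG methylation profiles. From bisulfite
    short reads it performs conversion-aware SNV genotyping and allele-stratified
    per-read methylation, detects epivariants (SNVs with allele-specific
    methylation) with Wilcoxon rank-sum tests under Benjamini-Hochberg FDR
    control, estimates total rDNA copy number from coverage ratios, quantifies
    per-read methylation entropy and its aging dynamics, and links methylation
    to rRNA allele frequencies including a methylation-adjusted allele-frequency
    prediction. A seeded synthetic-data generator emulates tandem rDNA arrays,
    long reads, bisulfite reads, rRNA counts, coverage tracks and aging cohorts
    so that every analysis is testable without external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    cluster,
    jsonlite,
    ape,
    vcfR,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
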