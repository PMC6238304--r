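Package: cyp2d6star
Title: CYP2D6 Star-Allele Diplotype Calling and Population Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calls CYP2D6 star-allele diplotypes from unphased SNP genotypes
    plus structural assay flags (whole-gene deletion, duplication, exon-9
    gene conversion) under a configurable allele-definition table, and
    summarises cohorts: allele, diplotype and SNP frequencies under
    hemizygote masking, metabolizer function-class burden, exact
    Hardy-Weinberg tests, and cross-population frequency comparison.
    Includes assay quality-control utilities (primer GC content and
    nearest-neighbor melting temperature, gene-versus-pseudogene
    discrimination by pairwise sequence identity) and a synthetic cohort
    generator so the whole pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    Biostrings,
    vcfR,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
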