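Package: xenopop
Title: Genomic Detection of Cross-Species Cloning and Hybrid Ancestry in Ant Colonies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting obligate cross-species sperm parasitism and
    male cloning (androgenesis) from multi-sample genotype data in harvester
    ants. Implements per-individual SNP heterozygosity screening for
    first-generation hybrids, supervised two-source ancestry estimation,
    rule-based separation of maternal and paternal haplomes of hybrid genomes
    against a low-diversity maternal reference, distance-based placement of
    haplomes and mitochondrial haplotypes onto species and lineage panels
    (including mito-nuclear mismatch detection and clonal-cluster discovery),
    synonymous and non-synonymous nucleotide diversity with bootstrap
    confidence intervals, and a synthetic colony generator with planted truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    stats,
    utils,
    vcfR
Suggests:
    jsonlite,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
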