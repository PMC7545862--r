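Package: MergeCall
Title: Comparing RNA-Seq Sample-Merging Strategies for SNP Detection
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to compare multi-sample RNA-seq merging strategies for SNP
    discovery. Implements a synthetic pileup cohort generator with known truth,
    count-based read pooling for three merging approaches (per-sample, merged
    by phenotype group and tissue, merged by phenotype group), a simplified
    multi-sample genotype-likelihood caller that reproduces pooled-sample
    allele dilution and Phred-quality inflation, a six-rule variant filter
    cascade (depth, alternative-allele support, gap proximity, site quality,
    INDEL proximity, allele frequency), variant-set partition and depth and
    quality effect-size comparison statistics, allele-frequency sharing
    curves, identification of SNPs fixed within a phenotype group, positional
    gene assignment, and hypergeometric gene-set enrichment with Bonferroni
    and Benjamini-Hochberg correction.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    withr,
    S4Vectors,
    GenomicRanges,
    IRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: VariantCalling, SNP, Transcriptomics, Software
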