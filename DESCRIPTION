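Package: rhmap
Title: Regional Heritability Mapping with Variance-Component Mixed Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Genome scan for regional genetic variance in case-control
    cohorts. Slides overlapping multi-SNP windows along the genome, fits a
    two-variance-component linear mixed model per window (whole-genome plus
    regional genomic relationship matrices) by average-information REML, and
    tests the regional variance with a boundary likelihood-ratio test against
    a 50-50 chi-square mixture. Includes PLINK and GCTA-format input/output,
    genotype quality control (call rate, minor allele frequency,
    Hardy-Weinberg exact test, linkage-disequilibrium pruning, relatedness),
    observed-to-liability heritability transformation for ascertained
    case-control designs, a companion single-SNP logistic-regression
    association scan with inflation diagnostics, and a liability-threshold
    cohort simulator with recorded ground truth for calibration and
    parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
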