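Package: crossASE
Title: Allele-Specific Expression Analysis for F1 Hybrid Crosses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis workflow for detecting allele-specific expression (ASE)
    in F1 hybrids of partially inbred mosquito colonies. Aggregates per-SNP
    allelic read counts to gene level by pseudo-phasing, tests genes against a
    simulated beta-binomial null with empirically estimated overdispersion,
    and applies false discovery rate control. Includes Mendelian-error
    parentage assignment from genotype matrices, sibling-based inference of
    informative SNPs, sample-swap diagnostics, permutation tests for the
    intersection of ASE gene sets across crosses, and enrichment statistics
    (copy-number confounding, selective sweeps, Wagner-parsimony gene ages,
    chromosome-arm effects, and cis-regulatory-module flanking assignment).
    A synthetic-cohort generator with known ground truth supports end-to-end
    validation without access to sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR,
    ape,
    IRanges,
    S4Vectors,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    phangorn
Config/testthat/edition: 3
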