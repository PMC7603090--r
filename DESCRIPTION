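Package: selsig
Title: Selection-Signature Scans in SNP Panels via Fst and XP-EHH
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects signatures of positive selection in genotyped
    populations, as used in livestock selection-signature studies. Provides
    chip-style SNP quality control (exact Hardy-Weinberg test, call rate,
    minor allele frequency, autosome filter), per-SNP Weir-Cockerham Fst,
    extended haplotype homozygosity (EHH) and cross-population EHH (XP-EHH)
    from phased haplotypes, empirical top-5% candidate calling, gene
    annotation of flanking candidate regions, population-structure summaries
    (pairwise-Fst neighbor-joining tree, genotype PCA), hypergeometric
    pathway over-representation, and a Balding-Nichols panel simulator with
    planted selective sweeps for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ape,
    vcfR,
    rtracklayer,
    GenomicRanges,
    IRanges
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
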