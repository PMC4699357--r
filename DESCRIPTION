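Package: popmeth
Title: Population Analysis of Twin Whole-Genome Bisulfite Sequencing Methylomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for population-scale whole-genome bisulfite
    sequencing (WGBS) analysis in twin cohorts. Reads Bismark-style cytosine
    reports, applies site-level quality filters (strand concordance,
    coverage-artifact blacklisting, SNP removal), segments merged-tissue
    methylomes into unmethylated and low-methylated regions, detects invariable
    CpGs and pairwise differentially methylated CpGs (Fisher's exact test),
    scores population differentially methylated regions with a sliding-window
    variance-and-consistency algorithm, decomposes methylation variance into
    additive-genetic and environmental components from monozygotic and
    dizygotic twin intra-class correlations, calls within-pair environmental
    DMRs with a permutation false discovery rate, tests inter-tissue epigenetic
    drift by direction concordance, annotates sites against CpG-island, genic
    and histone-mark features, and characterizes non-CpG (CpH) methylation.
    A twin-structured methylome simulator with known ground truth supports
    validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
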