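Package: nuiscan
Title: Discovery and Population Analysis of Non-Reference Unique Insertions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements an assembly-anchored pipeline for discovering
    breakpoint-resolved non-reference unique insertions (NUIs) from linked-read
    whole-genome data: extraction of unaligned and poorly aligned read pairs,
    stringent re-acceptance against diploid pseudo-haplotype assemblies, read
    cluster detection, anchored-contig breakpoint computation, the NUI
    definition filters (low-complexity and interspersed-repeat masking,
    known-reference and translocation screens, blacklist removal), cross-sample
    merging into a non-redundant catalog with an occurrence matrix,
    Alu-recombination-mediated deletion (ARMD) analysis with a consensus
    breakpoint-frequency statistic, orthogonal annotation (primate ancestry,
    transcription evidence, external call-set overlap), optical-map validation
    precision, and the population statistics layer (PCA, one-way ANOVA with
    Tukey HSD, exact tests). A synthetic-cohort generator with full ground
    truth supports end-to-end recovery testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
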