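Package: gisttools
Title: Genomic and Epigenomic Characterisation of Impure Low-Risk GIST Samples
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the desk-scale genomic characterisation of an impure
    tumour sample sequenced together with a matched normal, developed around
    very low-risk gastric gastrointestinal stromal tumours (GIST). Provides a
    purity-aware binomial model that classifies somatic mutations as founding
    (present in the majority of tumour cells) from alt-read counts, a
    somatic-variant filter cascade (strand support, sequencing depth, region
    and effect class, known polymorphisms), arm-level loss-of-heterozygosity
    detection and tumour-purity estimation from B-allele frequencies, an
    exact binomial enrichment test of screening-panel carrier counts against
    population minor-allele frequencies, a C2H2 zinc-finger motif scanner
    that maps amino-acid substitutions to structural positions, and
    reference-anchored methylation normalization with Pearson-correlation
    complete-linkage clustering. A synthetic-data module generates every
    input with known truth so all stages are testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    ape,
    withr
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    SummarizedExperiment,
    GenomicRanges,
    Biostrings,
    optparse
Config/testthat/edition: 3
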