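Package: mztrace
Title: Allele-Informed Analysis of the Maternal-to-Zygotic Transition and
    X/Y Sperm Omics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for tracing the maternal-to-zygotic transition (MZT) in
    fish embryos from hybrid crosses with informative parental SNP markers:
    selection of homozygous-divergent marker sites from parental genotypes,
    per-stage classification of embryo transcripts as maternal, zygotic or
    paternal from allele-specific read counts, detection of the zygotic
    activation time point, primordial-germ-cell relatedness screening by
    exact Spearman correlation, negative-binomial differential expression
    with empirical-Bayes dispersion moderation, and whole-genome bisulfite
    analysis of X versus Y sperm (CpG context summaries, windowed DMR
    calling, feature annotation, meta-profiles and methylation-expression
    integration). A synthetic-data generator with recorded ground truth
    makes every stage of the pipeline testable without external sequencing
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    vcfR,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
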