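Package: subclonedyn
Title: Subclonal Diversity Dynamics from Paired Tumor Samples
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infers subclonal diversity dynamics between a pretreatment
    tumor biopsy and the post-therapy resected tumor from paired somatic
    variant calls. Estimates per-sample tumor purity from somatic variant
    allele frequency (VAF) spectra reconciled with pathologist priors,
    counts purity-adjusted, detectability-filtered subclones and classifies
    them as lost, gained or retained, computes mutations-per-megabase
    spectrum curves by substitution class, and prioritizes candidate
    resistance variants with binomial evidence models. Ships a seeded
    clonal-evolution simulator (clone tree, therapy selection, spatial
    biopsy sampling, binomial read noise) that provides ground truth for
    recovery tests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    VariantAnnotation,
    SummarizedExperiment,
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
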