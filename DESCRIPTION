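Package: ascav
Title: Allele-Specific Chromatin Accessibility Variant Discovery and
    Interpretation
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Haplotype-aware discovery and interpretation of allele-specific
    chromatin accessibility variants (ASCAVs) and related allele-specific
    events (expression, histone modification, transcription-factor binding).
    Builds personalized diploid genomes from phased variants with exact
    coordinate maps, assigns reads to their haplotype of origin from paired
    alignments, counts alleles at phased heterozygous sites inside
    consolidated peak sets, and calls allelic imbalance with a WGS-informed
    two-tailed beta-binomial test plus copy-number-corrected allelic ratios.
    Downstream interpretation covers mutation copy-number timing relative to
    chromosomal gains, whole-genome-doubling classification, delta-PWM motif
    gain/loss scoring with Fisher enrichment against control variants,
    model-agnostic in silico saturation mutagenesis, and explained-fraction
    at fixed false-positive-rate analysis. A deterministic synthetic-data
    generator with full ground truth supports calibration and recovery
    testing of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    SummarizedExperiment,
    VariantAnnotation,
    rtracklayer,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: Epigenetics, ATACSeq, FunctionalGenomics, Sequencing,
    StatisticalMethod, CopyNumberVariation, MotifAnnotation
RoxygenNote: 7.3.3
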