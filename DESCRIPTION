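Package: scMRD
Title: Single-Cell Multi-Omics Selection and Longitudinal Monitoring of
    Leukemia-Specific Measurable Residual Disease Targets
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Identifies leukemia-specific measurable residual disease (MRD)
    targets in acute myeloid leukemia from single-cell DNA + surface-protein
    multi-omics data and monitors them longitudinally. Provides germline-SNP
    likelihood demultiplexing of multiplexed runs with doublet detection and
    quality-based cell removal, cell- and variant-level genotype filtering with
    zygosity-aware pseudobulk variant allele frequencies, genotype-defined
    clonal reconstruction with loss-of-heterozygosity detection, centered
    log-ratio immunophenotyping of clones, a five-criterion MRD target
    selection engine, droplet digital PCR limit-of-detection / rule-of-three
    positivity and ELN-style relapse calling with lead-time comparison, and a
    strand-aware beta-binomial error-corrected sequencing variant caller.
    A fully labeled synthetic cohort generator makes every stage testable
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    jsonlite,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: SingleCell, Sequencing, VariantDetection, ImmunoOncology
RoxygenNote: 7.3.3
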