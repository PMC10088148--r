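Package: mdswgs
Title: Whole-Genome Somatic Variant Survival Scanning and Prognostic
    Modelling for Transplant Cohorts
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Region-level survival association scanning of somatic variants
    for myelodysplastic syndrome (MDS) cohorts undergoing allogeneic
    hematopoietic cell transplantation: gene-based and sliding-window burden
    collapsing of multi-sample VCFs into carrier matrices, covariate-adjusted
    Cox and Fine-Gray genome scans with multiplicity control, unsupervised
    and outcome-guided (supervised) genomic subgrouping with cross-validated
    survival separation, and a random-survival-forest prognostic model ladder
    evaluated by Harrell's concordance and IPCW Brier scores. Includes a
    synthetic-cohort generator with planted proportional-hazards effects,
    competing risks and censoring, and a reproducible end-to-end pipeline
    with a digest-based manifest.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    survival,
    ranger,
    cluster,
    jsonlite,
    yaml,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    Biostrings,
    VariantAnnotation,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    cmprsk,
    mclust,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
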