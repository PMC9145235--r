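Package: shankvb
Title: Zone-Based Vascular-Bundle Phenotyping of Maize Shank Cross-Sections
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Phenotyping of vascular bundles in maize shank cross-section
    images partitioned into epidermis, periphery and inner functional zones,
    with a registry of 36 zone-resolved traits (areas, convex and
    circumcircle areas, axis lengths, perimeters, counts, densities,
    thicknesses and shape ratios), and the downstream quantitative analysis
    of a multi-environment inbred panel: fold-variation summaries, Spearman
    correlation with hierarchical trait clustering, one-way ANOVA with
    Duncan's multiple range test, EM-REML variance components with BLUP and
    broad-sense heritability, and a multi-method genome-wide association
    workflow (marker QC, marginal and PC-adjusted scans, hit intersection,
    SNP-to-gene annotation, shared-gene summaries and hypergeometric
    enrichment). Includes synthetic generators for cross-section images with
    ground truth, phenotype panels with known variance components, and
    genotype matrices with planted QTL, so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    GenomicRanges,
    IRanges,
    S4Vectors,
    grDevices,
    jsonlite,
    png,
    rtracklayer,
    stats,
    utils,
    vcfR,
    withr
Suggests:
    lme4,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
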