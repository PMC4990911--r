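Package: methinherit
Title: Intergenerational DNA Methylation Inheritance Analysis for RRBS
    and RNA-Seq Count Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for paternal epigenetic-inheritance studies:
    per-CpG differential methylation between exposed and control groups in
    sperm and intestinal epithelial cells across two generations, gene-level
    differential expression, genomic annotation of CpG sites, direction-
    concordant cross-set overlaps with a permutation null, methylation-
    expression quadrant integration, and MDS ordination with a permutation
    multivariate ANOVA. Includes a fully specified synthetic-data generator
    (beta-binomial bisulfite counts, negative-binomial expression counts)
    with planted inherited signals so every stage can be validated against
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    MASS,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer,
    fgsea
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
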