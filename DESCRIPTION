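Package: aneudose
Title: Detecting Gene Dosage Compensation in Aneuploid Strains from Paired RNA/DNA Read Counts
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for detecting dosage compensation of amplified genes in aneuploid
    versus euploid strains from paired RNA-seq and DNA-seq read counts. Implements
    RPKM and cell-count (spike-in) normalization with log2 ratio tables, a
    gene-specific threshold caller with permutation-based false discovery estimation,
    a mixture-of-linear-regressions dosage-response model fit by EM with
    maximum-posterior classification and conditional FDR, an independent per-gene
    likelihood-ratio proportionality test with Storey-style null-proportion
    estimation, an indirect-response (trans-effect) enrichment filter, and
    population CNV / buffering-score analyses. A seed-reproducible synthetic-data
    generator with known ground-truth dosage classes makes every stage testable
    without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    limma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
biocViews: Transcriptomics, GeneExpression, CopyNumberVariation, Normalization
RoxygenNote: 7.3.3
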