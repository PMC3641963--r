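Package: methnoise
Title: DNA Methylation and Transcriptional Noise Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Links gene body and promoter DNA methylation to transcriptional
    noise. Aggregates per-CpG bisulfite methylation calls into per-gene
    fractional methylation of TE-masked gene bodies, TE portions and promoter
    windows; estimates transcriptional noise as the coefficient of variation
    across curated replicate expression arrays; decomposes nested
    technical-within-biological replicate variation into biological and
    technical sums of squares; and fits a VIF-screened regression suite
    (ordinary least squares, Huber/bisquare/Hampel M-estimators, median
    quantile regression, sequential-SS ANOVA with individual-by-methylation
    interactions). A synthetic-data generator with planted effect sizes
    drives parameter-recovery and type-I validation of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    MASS,
    limma,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    car,
    optparse
Config/testthat/edition: 3
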