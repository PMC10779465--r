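Package: aaxscan
Title: Inter-Chromosome Additive-by-Additive Epistasis Scans for Quantitative Traits
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Genome-wide scanning of inter-chromosome additive-by-additive
    (AxA) epistasis effects on quantitative traits from SNP dosage data, as
    used in large-scale dairy cattle association studies.  Phenotypic yield
    deviations are pre-adjusted by polygenic predictions (approximate
    generalized least squares), two-locus genotype-class means are estimated
    by least squares, AxA values of the four allelic combinations and their
    contrast effect are computed with dosage weighting, and significance is
    assessed by t-tests with extreme-tail log10(1/p) evaluated in log space.
    Includes a synthetic-population generator with planted epistatic SNP
    pairs, chromosome-region bookkeeping of significant pairs, plot-ready
    data export, and a command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
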