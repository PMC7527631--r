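Package: scafqtl
Title: Assembly-Free GWAS and MultiQTL Modelling from Pooled Allele Frequencies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Association mapping for panels genotyped as pools, where each
    sample is scored by the frequency of the panel-wide major allele rather
    than by individual genotypes. Implements informative-marker selection for
    pooled nucleotide-frequency data, VanRaden genomic relationship matrices
    on the allele-frequency scale, principal coordinate and dendrogram views
    of population structure with Wright's FST between clusters, within-scaffold
    linkage-disequilibrium decay profiling to calibrate a marker collinearity
    threshold, kinship-corrected linear mixed model scans (REML variance
    components, Wald tests, effective-number-of-tests Bonferroni thresholds),
    forward-selection MultiQTL models that group collinear significant markers
    under representative markers, and matching of QTL regions across trial
    locations. A synthetic-panel generator reproduces the statistical structure
    such data exhibit (subpopulation differentiation, within-scaffold LD decay
    with a long-range floor, pooled sampling on a fixed allele-count grid,
    multi-location phenotypes with genotype-by-environment interaction) and
    carries the ground truth needed to score QTL recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ape,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
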