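Package: mqtlmed
Title: Multiple-Mediator Mediation of mQTL SNP Effects Through DNA Methylation
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Regression-based causal mediation analysis for binary disease
    outcomes with multiple continuous mediators, designed for methylation
    quantitative trait locus (mQTL) studies in which a risk SNP may act on
    disease through differential DNA methylation at several CpG sites
    simultaneously. Fits a logistic outcome model among cases and controls
    and linear mediator models among controls only (rare-disease
    approximation), decomposes the per-risk-allele odds ratio into natural
    direct and indirect effects with percentile-bootstrap confidence
    intervals, and supports exposure-mediator interaction in the
    single-mediator setting. Includes genotype quality control
    (Hardy-Weinberg, call rate), beta/M-value conversion, covariate
    encoding and exclusion bookkeeping for nested case-control designs,
    a synthetic-cohort generator with a closed-form oracle of the true
    effects, and a config-driven pipeline producing publication-style
    result tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
biocViews: Epigenetics, MethylationArray, SNP, Regression, QualityControl
RoxygenNote: 7.3.3
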