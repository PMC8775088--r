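Package: batchfst
Title: Detection and Quantification of Sequencing-Center Batch Effects in
    Multi-Center Genotype Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to detect and quantify technical batch effects attributable
    to the sequencing center in multi-center genotype cohorts. Implements
    per-individual counters of rare genomic events (consensus loss-of-function
    and benign variants, singletons, derived singletons, archaic introgressed
    alleles), a per-SNV between-center Weir-Cockerham Fst scan with equal-n
    subsampling and normalization by the maximum Fst attainable at the site's
    minor allele frequency, a Monte Carlo permutation null for the scaled-Fst
    profile with an observed-versus-null slope statistic, hierarchical mixed
    models on per-individual counts, correspondence analysis of the
    population-by-center sampling design, and pairwise Wilcoxon contrasts.
    Ships a seeded synthetic-cohort generator with center-specific genotype
    error injection so the whole pipeline can be exercised and calibrated
    without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    vcfR,
    lme4,
    lmerTest,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
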