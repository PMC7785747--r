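Package: sexmeta
Title: Sex-Dimorphic GWAS Meta-Analysis, Power, and Causal Inference
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Statistical machinery for sex-stratified genome-wide association
    meta-analysis of quantitative glycemic traits: inverse-variance fixed-effect
    pooling with genomic control, a two-degree-of-freedom sex-dimorphic
    chi-square test, Cochran's Q and I-squared heterogeneity statistics, locus
    discovery and novelty classification, two-SNP approximate conditional
    analysis from summary statistics, power simulation with a noncentral
    chi-square analytic oracle, bidirectional two-sample Mendelian
    randomization (random-effect IVW and MR-Egger), and sex-interaction
    expression models. A seeded synthetic-data layer generates every input the
    pipeline consumes so all stages run without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    metafor,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
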