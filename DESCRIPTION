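Package: conifergs
Title: Genomic Selection and Marker-Density Experiments for Conifer
    Progeny Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis toolkit for pedigree-based and
    genomic prediction in forest-tree progeny trials. Generates synthetic
    multi-site trial populations for two classical conifer designs
    (full-sib partial diallels and open-pollinated half-sib families),
    builds numerator relationship matrices and status-number effective
    population sizes from pedigrees, fits the corresponding linear mixed
    models by EM-REML and Henderson's mixed-model equations to obtain
    estimated breeding values (ABLUP), fits ridge-regression BLUP
    (RR-BLUP) marker-effect models with a dual-form solver for wide
    genotype matrices, and orchestrates replicated marker-density
    cross-validation experiments with accuracy summaries, plateau and
    marker-requirement calculators.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
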