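Package: trajbpp
Title: Trajectory Subgroup Posterior Probabilities as Quantitative Traits
    for Gene Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Maps genes affecting longitudinal phenotypes such as systolic
    blood pressure. Repeated measurements are clustered into latent
    trajectory subgroups with a finite mixture of polynomial growth curves
    fitted by EM; the number of subgroups is chosen by BIC after a two-run
    polynomial-order pruning step. Each individual's Bayesian posterior
    probability (BPP) of belonging to the clinically relevant subgroup is
    then used as a quantitative trait in population-based Wald regression
    with false-discovery-rate control, and in family-based tests
    (within-family permutation regression and a transmission
    disequilibrium test on the dichotomized BPP). Power is evaluated with
    a replicate-set procedure: one discovery plus two confirmatory
    replicates per set, per-gene YES/NO scoring, and null regions for
    empirical type-I error. A seeded simulator generates pedigree and
    unrelated cohorts with SNP genotypes and replicate longitudinal
    phenotypes for method evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3), SummarizedExperiment, GenomicRanges
Imports: methods, stats, utils, tools, S4Vectors, IRanges, jsonlite,
    MASS, pracma
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
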