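Package: poolGBS
Title: Temporal Genetic Dynamics and Forage Yield of Sown Swards from
    Pooled Genotyping-by-Sequencing
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis of temporal genetic dynamics in the perennial
    ryegrass component of sown grass-clover swards from pooled
    genotyping-by-sequencing (pool-GBS) read counts. Implements Bayesian
    per-sample allele-frequency estimation on a discrete frequency grid
    with a folded Watterson-theta prior and posterior fixation rules, a
    simplified Watterson theta estimator from pooled read counts, the SNP
    filter cascade (depth, missingness, multi-allelic, allele-frequency
    band), expected-heterozygosity time series with sequential ANOVA,
    centred unscaled PCA of allele frequencies, cultivar-private SNP
    detection and cultivar-abundance tracking, a per-SNP sequential
    variance-decomposition selection scan with a maximum-likelihood
    empirical null, pool-versus-individual validation metrics, and
    grass-clover yield mixed models with likelihood-ratio tests. A
    synthetic-trial generator with full ground truth supports
    parameter-recovery and calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    VariantAnnotation,
    MASS,
    lme4
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
biocViews: Genetics, SNP, Sequencing, PopulationGenetics
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'design.R'
    'io.R'
    'simulate.R'
    'poolAF.R'
    'filters.R'
    'validation.R'
    'diversity.R'
    'scan.R'
    'yield.R'
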