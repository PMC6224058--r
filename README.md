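# poolGBS

Temporal genetic dynamics and forage yield of sown ryegrass–clover
swards, analysed from pooled genotyping-by-sequencing (pool-GBS) read
counts.

Agricultural grasslands are sown as mixtures of species and cultivars,
and the genetic composition of the sward keeps changing after sowing.
This package is for quantitative geneticists and grassland researchers
who track those changes with pool-GBS: instead of genotyping plants one
by one, equal amounts of leaf tissue from 40 plants per plot are pooled,
sequenced, and population allele frequencies are read directly from the
allelic read depths. The package covers the full downstream analysis of
a multi-year sward trial (7 seed compositions × 2 replicate plots ×
4 years = 56 population samples, pooled in replicate into 112 libraries):

* **Allele-frequency estimation** — a Bayesian posterior on the discrete
  pool-frequency grid `f = k/80` with binomial read likelihood,
  sequencing-error rate, and a folded Watterson-theta prior; posterior
  fixation rules snap error-driven calls to 0 or 1
  (`estimateTheta()`, `posteriorAF()`, `applyFixationRules()`,
  `estimateAAF()`).
* **Locus filtering** — the depth / total-depth / missingness /
  multi-allelic / allele-frequency-band cascade with a per-step report
  (`filterCascade()`), plus read-depth saturation curves
  (`saturationCurve()`).
* **Diversity dynamics** — expected heterozygosity
  `He = 2·AAF·(1−AAF)` time series with the sequential ANOVA
  `mean He ~ S + S:R + S:Y`; centred unscaled PCA of the AAF matrix;
  cultivar-private SNP detection and cultivar-abundance trajectories
  (`heterozygosity()`, `anovaMeanHe()`, `pcaAAF()`, `privateSNPs()`,
  `cultivarAbundance()`).
* **Selection scan** — per-SNP sequential variance decomposition
  `AAF ~ PC1 + S + S:R + S:Y`, the mean-square ratio
  `MSS(S×Y)/MSS(residual)` as statistic, a maximum-likelihood empirical
  null (log-normal / gamma / chi-square / F, AIC-selected), BH-FDR calls
  and a KS uniformity diagnostic (`decomposeVariance()`, `scanAAF()`,
  `fitNull()`, `pvaluesAndCalls()`, `selectionScan()`).
* **Yield models** — herbage dry-matter arithmetic, botanical fractions,
  and the three cultivar-effect hypotheses via `lme4` mixed models with
  likelihood-ratio tests (`dryMatterWeight()`, `botanicalFractions()`,
  `fitYieldModel()`, `likelihoodRatioTest()`, `yieldHypothesisTests()`).
* **Synthetic trials** — a generator with complete ground truth (founder
  cultivars, private loci, cultivar-proportion trajectories, optional
  selected loci, 40-plant sampling, read sampling) for calibration and
  parameter-recovery studies (`simulationConfig()`, `simulateTrial()`,
  `simulateYield()`).
* **Validation metrics** — pool-vs-individual AAF agreement, genotype
  concordance across technical replicates, SNP-set Venn intersections,
  and AAF spectra of reproducible vs non-reproducible calls
  (`compareAAF()`, `genotypeConcordance()`, `snpSetIntersections()`,
  `spectrumByReproducibility()`).

Data containers are Bioconductor classes: `PoolCounts`, `PoolAAF` and
`GenotypeCalls` extend `RangedSummarizedExperiment`, with the trial
design in `colData` and TSV/VCF readers and writers
(`readCountTable()`, `readGenotypeVcf()`, `readDesignTable()`,
`readYieldTable()`, ...). A thin command-line wrapper lives in
`inst/scripts/poolgbs-cli.R`.

## Worked example

```r
library(poolGBS)

cfg <- simulationConfig(n_loci = 5000, seed = 42)
trial <- simulateTrial(cfg)
trial$counts
#> PoolCounts: 5000 loci x 56 samples
#>   median total depth: 98

aaf <- estimateAAF(trial$counts)
filtered <- filterCascade(trial$counts, aaf, filterConfig("pool"))
filtered$report
#>           step loci masked_cells
#> 1        input 5000           12
#> 2  total_depth 5000           NA
#> 3      missing 4988           NA
#> 4 multiallelic 4988           NA
#> 5     aaf_band 3888           NA

div <- heterozygosity(filtered$aaf)
anovaMeanHe(div, trialDesign())
#>        term df       sum_sq      mean_sq    statistic      p_value
#> 1         S  6 2.915804e-02 4.859674e-03 1770.2932836 2.846063e-27
#> 2       S:R  7 2.167361e-05 3.096230e-06    1.1279018 3.832394e-01
#> 3       S:Y 21 2.711324e-05 1.291107e-06    0.4703274 9.543469e-01
#> 4 Residuals 21 5.764759e-05 2.745123e-06           NA           NA

pcaAAF(filtered$aaf)
#> PCA of AAF matrix: 56 samples, 56 components; PC1 explains 78.3%

scan <- selectionScan(filtered$aaf)
scan$fits
#> lognormal  AIC 5710.7    (meanlog=0.02519, sdlog=0.4915)
#> gamma      AIC 5879.7    (shape=4.282, rate=3.699)
#> chisquare  AIC 9874.2    (=1.894)
#> f          AIC 5707.6 *  (df1=20.04, df2=15.6)
cat(sprintf("KS uniformity p = %.2f; outliers at FDR 0.05: %d\n",
            scan$calls$ks_p, scan$calls$n_outliers))
#> KS uniformity p = 0.10; outliers at FDR 0.05: 0

merks  <- privateSNPs(filtered$aaf, "Merks")    # 325 loci
meloni <- privateSNPs(filtered$aaf, "Meloni")   # 374 loci
ab <- cultivarAbundance(filtered$aaf, merks, meloni)
round(tapply(ab$w_merks[ab$composition >= 5],
             ab$year[ab$composition >= 5], mean), 2)
#>    1    2    3    4
#> 0.59 0.38 0.41 0.61
```

Reading the output: the seed mixtures separate cleanly on PC1 (~78% of
the AAF variance — the cultivar axis); the diversity ANOVA attributes
mean-He variation to seed composition (S) with no replicate-consistent
temporal signal (S:Y, p = 0.95), as expected for this neutral
simulation; the scan's empirical null fits, p-values are uniform and no
outliers are called; and the Merks proportion in mixed plots recovers
the generator's non-monotone trajectory (prominent in years 1 and 4,
receding in years 2 and 3).

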