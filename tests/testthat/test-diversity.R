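test_that("expected heterozygosity formula, symmetry, bounds", {
    he <- heterozygosity(matrix(c(0.5, 0, 1, 0.25), 4, 1))
    expect_equal(unname(he$he[, 1]), c(0.5, 0, 0, 0.375))

    p <- seq(0, 1, by = 0.01)
    expect_equal(heterozygosity(matrix(p))$he,
                 heterozygosity(matrix(1 - p))$he)
    expect_true(all(heterozygosity(matrix(p))$he <= 0.5))

    ## mean over non-missing loci only
    m <- matrix(c(0.5, NA, 0.5), 3, 1)
    expect_equal(unname(heterozygosity(m)$mean_he), 0.5)
})

test_that("mean-He ANOVA has the full-design degrees of freedom", {
    d <- trialDesign()
    set.seed(15)
    tab <- anovaMeanHe(rnorm(56, 0.3, 0.02), d)
    expect_identical(tab$df, c(6L, 7L, 21L, 21L))
    expect_identical(sum(tab$df), 55L)
    expect_identical(tab$term, c("S", "S:R", "S:Y", "Residuals"))

    ## constant response: all sums of squares vanish
    tab0 <- anovaMeanHe(rep(0.3, 56), d)
    expect_true(all(abs(tab0$sum_sq) < 1e-25))

    ## pure composition effect, no noise: everything lands in S
    y <- 0.1 + 0.01 * d$composition
    tabS <- anovaMeanHe(y, d)
    expect_gt(tabS$sum_sq[1], 1e-6)
    expect_lt(sum(tabS$sum_sq[-1]), 1e-20)

    ## sequential SS conserve the total
    y2 <- rnorm(56)
    t2 <- anovaMeanHe(y2, d)
    expect_equal(sum(t2$sum_sq), sum((y2 - mean(y2))^2))
})

test_that("PCA separates disjoint profiles and fixes the PC1 sign", {
    d <- trialDesign()
    set.seed(16)
    ## synthetic trial: PC1 should order samples by true Merks proportion
    cfg <- simulationConfig(n_loci = 1500, seed = 16)
    tr <- simulateTrial(cfg)
    truth_aaf <- tr$truth$sample_aaf
    pc <- pcaAAF(truth_aaf, design = d)
    expect_gt(pc$variance_explained[1], 0.5)
    expect_true(all(diff(pc$variance_explained) <= 1e-12))
    ## sign convention: pure-Merks samples negative on average
    expect_lt(mean(pc$scores[d$ryegrass_content == "Merks", 1]), 0)
    ## mixtures sit between the pure clusters, ordered by true w
    merks_mean <- mean(pc$scores[d$ryegrass_content == "Merks", 1])
    meloni_mean <- mean(pc$scores[d$ryegrass_content == "Meloni", 1])
    mix <- d$ryegrass_content == "both"
    expect_true(all(pc$scores[mix, 1] > merks_mean &
                    pc$scores[mix, 1] < meloni_mean))
    expect_lt(cor(pc$scores[mix, 1], tr$truth$w[mix]), -0.8)

    ## permutation invariance: shuffling samples permutes the scores
    perm <- sample(56)
    pc2 <- pcaAAF(truth_aaf[, perm], design = d[perm, ])
    expect_equal(abs(pc2$scores[, 1]), abs(pc$scores[perm, 1]),
                 tolerance = 1e-8)

    expect_error(pcaAAF(matrix(c(NA, 0.5), 1, 2)), "missing")
})

test_that("mixing two cultivars does not lower expected diversity", {
    cfg <- simulationConfig(n_loci = 3000, seed = 17)
    pr <- simulateCultivars(cfg)
    mix <- 0.5 * pr$merks + 0.5 * pr$meloni
    meanHe <- function(p) mean(2 * p * (1 - p))
    expect_gte(meanHe(mix), max(meanHe(pr$merks), meanHe(pr$meloni)))
    ## larger founder base -> Merks at least as diverse as Meloni
    expect_gte(meanHe(pr$merks), meanHe(pr$meloni))
})

test_that("private SNP definition on hand-built samples", {
    d <- trialDesign()
    ## locus 1: zero in all pure-Meloni samples, 0.3 somewhere in Merks
    ## locus 2: 0.01 in one pure-Meloni sample -> not Merks-private
    ## locus 3: zero everywhere -> not private to anyone
    m <- matrix(0, 3, 56, dimnames = list(NULL, d$sample_id))
    merks_cols <- which(d$ryegrass_content == "Merks")
    meloni_cols <- which(d$ryegrass_content == "Meloni")
    m[1, merks_cols[1]] <- 0.3
    m[2, merks_cols] <- 0.4
    m[2, meloni_cols[1]] <- 0.01
    aaf <- makeAAF(m, samples = d$sample_id, design = d)
    got <- privateSNPs(aaf, "Merks")
    expect_identical(got, rownames(aaf)[1])
    expect_error(privateSNPs(makeAAF(m[, merks_cols],
                                     samples = d$sample_id[merks_cols],
                                     design = d[merks_cols, ]), "Merks"),
                 "no pure")
})

test_that("private SNPs recovered from a simulated trial with high
           precision", {
    cfg <- simulationConfig(n_loci = 4000, seed = 18)
    tr <- simulateTrial(cfg)
    aaf <- estimateAAF(tr$counts)
    ## the full pool preset: the mean-AAF band is the designed defence
    ## against error-read SNPs posing as private loci
    fc <- filterCascade(tr$counts, aaf, filterConfig("pool"))
    keys <- rownames(tr$truth$pop_af)
    true_m <- keys[tr$truth$profiles$private_merks]
    true_l <- keys[tr$truth$profiles$private_meloni]
    got_m <- privateSNPs(fc$aaf, "Merks")
    got_l <- privateSNPs(fc$aaf, "Meloni")
    ## precision: recovered loci are overwhelmingly truly private
    expect_gt(mean(got_m %in% true_m), 0.9)
    expect_gt(mean(got_l %in% true_l), 0.9)
    ## recall over true private loci that survived the filters: strict
    ## privacy (AAF exactly 0 in every pure sample of the other cultivar)
    ## is occasionally spoiled when >= 2 error reads land on one of the 16
    ## pure-other samples, so a few percent of loci are forfeited
    panel_m <- intersect(true_m, rownames(fc$aaf))
    panel_l <- intersect(true_l, rownames(fc$aaf))
    expect_gt(mean(panel_m %in% got_m), 0.85)
    expect_gt(mean(panel_l %in% got_l), 0.85)
})

test_that("cultivar abundance recovers the mixing proportion", {
    ## deterministic 50:50 mixtures: w_hat for mixed plots near 1/2,
    ## pure plots normalized to 1 on average
    cfg <- simulationConfig(n_loci = 4000, seed = 19,
                            trajectory = list(year_logit = rep(0, 4),
                                              composition_logit = c(0, 0, 0),
                                              plot_sd = 0))
    tr <- simulateTrial(cfg)
    aaf <- estimateAAF(tr$counts)
    fc <- filterCascade(tr$counts, aaf, filterConfig("pool"))
    pm <- privateSNPs(fc$aaf, "Merks")
    pl <- privateSNPs(fc$aaf, "Meloni")
    ab <- cultivarAbundance(fc$aaf, pm, pl)
    d <- trialDesign()
    pure_m <- d$ryegrass_content == "Merks"
    expect_equal(mean(ab$w_merks[pure_m]), 1, tolerance = 1e-9)
    mixed <- d$ryegrass_content == "both"
    expect_lt(abs(mean(ab$w_merks[mixed]) - 0.5), 0.05)
    expect_lt(abs(mean(ab$w_meloni[mixed]) - 0.5), 0.05)
    expect_error(cultivarAbundance(fc$aaf, character(0), pl), "non-empty")
})
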