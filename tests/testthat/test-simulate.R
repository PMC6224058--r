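test_that("cultivar AFs sit on the founder grid and honour private sets", {
    cfg <- simulationConfig(n_loci = 3000, founders = c(merks = 2,
                                                        meloni = 2),
                            seed = 3)
    pr <- simulateCultivars(cfg)
    grid <- (0:4) / 4
    expect_true(all(pr$merks %in% grid))
    expect_true(all(pr$meloni %in% grid))
    ## private invariant: focal segregating, other exactly zero
    expect_true(all(pr$merks[pr$private_merks] > 0))
    expect_true(all(pr$meloni[pr$private_merks] == 0))
    expect_true(all(pr$meloni[pr$private_meloni] > 0))
    expect_true(all(pr$merks[pr$private_meloni] == 0))
})

test_that("private locus counts follow the configured fractions", {
    n <- 10000L
    cfg <- simulationConfig(n_loci = n,
                            private_fraction = c(merks = 0.02,
                                                 meloni = 0.05),
                            seed = 9)
    pr <- simulateCultivars(cfg)
    ## binomial tolerance: 4 sd around n * fraction for the seeded sets
    tol <- function(p) 4 * sqrt(n * p * (1 - p))
    expect_lt(abs(length(pr$seeded_merks) - n * 0.02), tol(0.02))
    expect_lt(abs(length(pr$seeded_meloni) - n * 0.05), tol(0.05))
    ## chance fixation only ever adds private loci
    expect_true(all(pr$seeded_merks %in% pr$private_merks))
    expect_true(all(pr$seeded_meloni %in% pr$private_meloni))
})

test_that("simulation is deterministic given config and seed", {
    cfg <- simulationConfig(n_loci = 200, seed = 77)
    t1 <- simulateTrial(cfg)
    t2 <- simulateTrial(cfg)
    expect_identical(refCounts(t1$counts), refCounts(t2$counts))
    expect_identical(altCounts(t1$counts), altCounts(t2$counts))
    expect_identical(t1$truth$w, t2$truth$w)
    expect_identical(simulateYield(seed = 5), simulateYield(seed = 5))
})

test_that("full design yields 56 sample columns; monocultures have fixed w", {
    cfg <- simulationConfig(n_loci = 50, seed = 2)
    tr <- simulateTrial(cfg)
    expect_identical(ncol(tr$counts), 56L)
    d <- trialDesign()
    expect_true(all(tr$truth$w[d$ryegrass_content == "Merks"] == 1))
    expect_true(all(tr$truth$w[d$ryegrass_content == "Meloni"] == 0))
    mixed <- tr$truth$w[d$ryegrass_content == "both"]
    expect_true(all(mixed > 0 & mixed < 1))
})

test_that("pooled AAF of a 50:50 mixture equals w times the cultivar AF", {
    ## Merks-private loci at AF 0.4 in a deterministic 50:50 mixture:
    ## expected pool AAF = 0.5 * 0.4 = 0.20, checked by averaging
    ## thousands of independently sampled loci
    n <- 4000L
    profiles <- structure(list(merks = rep(0.4, n), meloni = rep(0, n),
                               private_merks = seq_len(n),
                               private_meloni = integer(0)),
                          class = "CultivarProfiles")
    cfg <- simulationConfig(n_loci = n, seed = 21,
                            trajectory = list(year_logit = rep(0, 4),
                                              composition_logit = c(0, 0, 0),
                                              plot_sd = 0))
    d <- trialDesign()[trialDesign()$composition == 5, ][1, , drop = FALSE]
    tr <- simulateTrial(cfg, design = d, profiles = profiles)
    expect_equal(unname(tr$truth$w), 0.5)
    ## 40-plant sampling error per locus ~ sqrt(.16/80); mean over 4000 loci
    expect_lt(abs(mean(tr$truth$sample_aaf) - 0.20), 0.005)
    ## and the realized read fractions agree
    frac <- altCounts(tr$counts) / (refCounts(tr$counts) +
                                    altCounts(tr$counts))
    expect_lt(abs(mean(frac, na.rm = TRUE) - 0.20), 0.01)
})

test_that("read fractions converge to the sample AAF at high depth", {
    cfg <- simulationConfig(n_loci = 800, seed = 13, depth_mean = 5000,
                            depth_dispersion = 1e6, error_rate = 0)
    d <- trialDesign()[1:4, ]
    tr <- simulateTrial(cfg, design = d)
    frac <- altCounts(tr$counts) / (refCounts(tr$counts) +
                                    altCounts(tr$counts))
    expect_lt(mean(abs(frac - tr$truth$sample_aaf)), 0.01)
})

test_that("per-plant genotypes are consistent with the pooled dose", {
    cfg <- simulationConfig(n_loci = 300, seed = 4)
    d <- trialDesign()[1:2, ]
    tr <- simulateTrial(cfg, design = d, genotypes = d$sample_id[1])
    g <- tr$genotypes[[d$sample_id[1]]]
    expect_s4_class(g, "GenotypeCalls")
    expect_identical(ncol(g), 40L)
    expect_equal(unname(rowSums(genoCalls(g)) / 80),
                 unname(tr$truth$sample_aaf[, 1]))
})

test_that("yield generator: additivity, conservation, zero-noise limits", {
    zero <- c(replicate = 0, year = 0, residual = 0, fraction = 0)
    eff0 <- yieldEffects(mu = 8,
                         ryegrass = c(Merks = 0, Meloni = 0, both = 0),
                         clover_presence = 0,
                         clover = c(none = 0, both = 0, Lemmon = 0,
                                    Crossway = 0))
    y0 <- simulateYield(effects = eff0, varcomp = zero, seed = 1)
    expect_true(all(y0$dmw_total == 8))

    ## clover presence +2, everything else flat: compositions 3 and 4
    ## exceed 1 and 2 by exactly 2
    eff2 <- yieldEffects(mu = 8,
                         ryegrass = c(Merks = 0, Meloni = 0, both = 0),
                         clover_presence = 2,
                         clover = c(none = 0, both = 0, Lemmon = 0,
                                    Crossway = 0))
    y2 <- simulateYield(effects = eff2, varcomp = zero, seed = 1)
    m <- tapply(y2$dmw_total, y2$composition, mean)
    expect_equal(unname(m[["3"]] - m[["1"]]), 2)
    expect_equal(unname(m[["4"]] - m[["2"]]), 2)

    ## grass + clover + weed fractions conserve mass
    y <- simulateYield(seed = 11)
    expect_equal(y$grass_fraction + y$clover_fraction + y$weed_fraction,
                 rep(1, nrow(y)))
    expect_equal(y$dmw_grass + y$dmw_clover, y$dmw_total)
    ## monocultures are pure grass
    expect_true(all(y$grass_fraction[y$composition %in% 1:2] == 1))
})
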