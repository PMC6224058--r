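## hand-enumerated 5-locus toy: A fails the AAF band, B is multi-allelic,
## C has a shallow cell (-> missing, pool mode tolerates none), D/E clean
toyCascadeInput <- function() {
    ref <- rbind(A = c(95, 95, 95), B = c(50, 50, 50), C = c(15, 50, 50),
                 D = c(50, 50, 50), E = c(50, 50, 50))
    alt <- rbind(A = c(5, 5, 5), B = c(50, 50, 50), C = c(5, 50, 50),
                 D = c(50, 50, 50), E = c(50, 50, 50))
    extra <- rbind(A = c(0, 0, 0), B = c(0, 3, 0), C = c(0, 0, 0),
                   D = c(0, 0, 0), E = c(0, 0, 0))
    counts <- makeCounts(ref, alt, extra)
    aaf <- makeAAF(rbind(c(0.05, 0.05, 0.05), c(0.5, 0.5, 0.5),
                         c(0.25, 0.5, 0.5), c(0.5, 0.5, 0.5),
                         c(0.5, 0.5, 0.5)))
    list(counts = counts, aaf = aaf)
}

test_that("filter cascade applies the steps in order with an auditable
           report", {
    toy <- toyCascadeInput()
    out <- filterCascade(toy$counts, toy$aaf, filterConfig("pool"))
    expect_identical(out$report$step,
                     c("input", "total_depth", "missing", "multiallelic",
                       "aaf_band"))
    expect_identical(out$report$loci, c(5L, 5L, 4L, 3L, 2L))
    expect_identical(nrow(out$aaf), 2L)
    expect_identical(out$report$masked_cells[1], 1L)  # the shallow cell
})

test_that("clean input passes through unchanged", {
    m <- matrix(0.5, 4, 3)
    counts <- makeCounts(matrix(30L, 4, 3), matrix(30L, 4, 3))
    aaf <- makeAAF(m)
    out <- filterCascade(counts, aaf, filterConfig("pool"))
    expect_equal(aafValues(out$aaf), aafValues(aaf))
})

test_that("AAF band bounds are inclusive by default, strict on request", {
    counts <- makeCounts(matrix(30L, 3, 2), matrix(30L, 3, 2))
    aaf <- makeAAF(rbind(c(0.10, 0.10), c(0.90, 0.90), c(0.05, 0.05)))
    out <- filterCascade(counts, aaf, filterConfig("pool"))
    expect_identical(nrow(out$aaf), 2L)     # 0.10 and 0.90 retained
    strict <- filterConfig("pool", band_inclusive = FALSE)
    expect_warning(out2 <- filterCascade(counts, aaf, strict), "no loci")
    expect_identical(nrow(out2$aaf), 0L)
})

test_that("the cascade is idempotent", {
    set.seed(8)
    depth <- matrix(rnbinom(300, mu = 60, size = 3), 50, 6)
    alt <- matrix(rbinom(300, depth, runif(300)), 50, 6)
    counts <- makeCounts(depth - alt, alt)
    aaf <- makeAAF(ifelse(depth > 0, alt / depth, NA))
    cfg <- filterConfig("pool", max_missing = 2)
    once <- filterCascade(counts, aaf, cfg)
    twice <- filterCascade(once$counts, once$aaf, cfg)
    expect_identical(aafValues(twice$aaf), aafValues(once$aaf))
    expect_identical(nrow(twice$counts), nrow(once$counts))
})

test_that("tightening any threshold never increases surviving loci", {
    set.seed(9)
    depth <- matrix(rnbinom(1000, mu = 80, size = 5), 100, 10)
    alt <- matrix(rbinom(1000, depth, rep(runif(100), 10)), 100, 10)
    counts <- makeCounts(depth - alt, alt)
    aaf <- makeAAF(ifelse(depth > 0, alt / depth, NA))
    surv <- function(...) {
        cfg <- filterConfig("pool", ...)
        suppressWarnings(nrow(filterCascade(counts, aaf, cfg)$aaf))
    }
    ## sweep min_depth with the band off: re-masking cells changes the
    ## per-locus mean AAF, so monotonicity is a per-threshold guarantee
    expect_true(all(diff(vapply(c(10, 30, 50, 70),
        function(md) surv(min_depth = md, max_missing = 10,
                          aaf_band = NULL),
        integer(1))) <= 0))
    expect_true(all(diff(vapply(c(10, 5, 2, 0),
        function(mm) surv(max_missing = mm), integer(1))) <= 0))
    expect_true(all(diff(vapply(list(c(0, 1), c(.1, .9), c(.3, .7)),
        function(b) surv(aaf_band = b, max_missing = 10),
        integer(1))) <= 0))
})

test_that("saturation curves are nested-monotone and match the binomial
           tail for uniform reads", {
    ## degenerate cases
    one_pos <- rep(1L, 1000)
    sat <- saturationCurve(one_pos, grid = c(0, 1000),
                           thresholds = c(10, 300))
    expect_true(all(sat$positions[sat$reads == 0] == 0L))
    expect_true(all(sat$positions[sat$reads == 1000] == 1L))

    ## monotone in reads, anti-monotone in threshold
    set.seed(10)
    reads <- sample.int(500, 20000, replace = TRUE)
    sat2 <- saturationCurve(reads, grid = c(1000, 5000, 10000, 20000))
    for (t in unique(sat2$threshold))
        expect_true(all(diff(sat2$positions[sat2$threshold == t]) >= 0))
    for (g in unique(sat2$reads))
        expect_true(all(diff(sat2$positions[sat2$reads == g]) <= 0))

    ## 3000 uniform reads over 100 positions at threshold 30: expected
    ## count from the exact binomial tail, within 4 sd
    set.seed(11)
    unif <- sample.int(100, 3000, replace = TRUE)
    sat3 <- saturationCurve(unif, grid = 3000, thresholds = 30)
    p <- pbinom(29, 3000, 1 / 100, lower.tail = FALSE)
    expect_lt(abs(sat3$positions - 100 * p), 4 * sqrt(100 * p * (1 - p)))
})
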