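## Bayesian allele-frequency estimation from pooled read counts.
##
## The estimator follows the SNAPE-pooled recipe at contract level: a
## discrete posterior over pool allele frequencies f_k = k/C (C = number of
## pooled chromosomes), binomial read likelihood with a symmetric
## sequencing error rate, and a folded informative prior built from a
## per-sample Watterson theta. Interior grid points carry prior mass
## proportional to theta * (1/f + 1/(1-f)), normalized so the total
## interior mass is min(1, theta * a_n); the remainder is split equally
## between the fixed-reference (f = 0) and fixed-alternative (f = 1)
## boundary points, whose posterior masses are reported as p0 and p1.

harmonicNumber <- function(n) sum(1 / seq_len(n))

#' Simplified Watterson theta from pooled read counts
#'
#' Per-sample diversity estimate used as the prior scale of
#' [posteriorAF()]: `theta = S / (L * a_n)`, where `L` is the number of
#' sites with total read depth at least `min_depth`, `S` the number of
#' those at which the minor allele is supported by at least `mac` reads,
#' and `a_n` the harmonic number `sum(1/i, i = 1..n-1)` with `n` the number
#' of pooled chromosomes (80 for 40 diploid plants).
#'
#' @param counts a [PoolCounts] object.
#' @param sample sample id (column) to estimate.
#' @param mac minimum minor-allele read count for a site to be counted as
#'   segregating (default 3).
#' @param min_depth minimum total read depth for a site to be assessed
#'   (default 30).
#' @param n_plants diploid pool size (default 40).
#' @return list of class `ThetaEstimate`: `theta`, `n_segregating`,
#'   `n_sites`, `mac`, `n_chromosomes`.
#' @export
estimateTheta <- function(counts, sample, mac = 3L, min_depth = 30L,
                          n_plants = 40L) {
    stopifnot(mac >= 1L)
    r <- refCounts(counts)[, sample]
    a <- altCounts(counts)[, sample]
    depth <- r + a
    ok <- !is.na(depth) & depth >= min_depth
    L <- sum(ok)
    if (L == 0L)
        stop("no assessable sites: none reach depth ", min_depth,
             " in sample ", sample)
    S <- sum(pmin(r[ok], a[ok]) >= mac)
    nchrom <- 2L * n_plants
    est <- list(theta = S / (L * harmonicNumber(nchrom - 1L)),
                n_segregating = S, n_sites = L, mac = as.integer(mac),
                n_chromosomes = nchrom)
    class(est) <- "ThetaEstimate"
    est
}

#' @export
print.ThetaEstimate <- function(x, ...) {
    cat("Watterson theta:", signif(x$theta, 4), "(", x$n_segregating,
        "segregating of", x$n_sites, "sites, MAC", x$mac, ",",
        x$n_chromosomes, "chromosomes )\n")
    invisible(x)
}

#' Grid posterior for the pooled alternative-allele frequency
#'
#' Computes, per site, the posterior distribution of the pool allele
#' frequency on the discrete grid `k / pool_chromosomes` under a binomial
#' read likelihood with symmetric error rate and the folded informative
#' theta prior described above. The point estimate is the posterior mean;
#' `p0` and `p1` are the posterior masses of the fixed-reference and
#' fixed-alternative boundary points used by the fixation rules.
#'
#' @param ref,alt reference and alternative read counts (vectors).
#' @param theta a [estimateTheta()] result or a plain number.
#' @param error_rate symmetric per-read error probability in `[0, 0.5)`.
#' @param pool_chromosomes chromosomes in the pool (80 for 40 diploids).
#' @param grid_points number of grid points (default
#'   `pool_chromosomes + 1`; larger values refine the grid).
#' @param details also attach the full posterior: attributes `grid` (the
#'   frequency grid) and `posterior` (sites x grid matrix).
#' @return data.frame with one row per site: `aaf_estimate`, `p0`, `p1`,
#'   `depth`. Sites with `ref + alt == 0` get `NA` throughout.
#' @export
#' @examples
#' posteriorAF(30, 30, theta = 0.01)
posteriorAF <- function(ref, alt, theta, error_rate = 0.001,
                        pool_chromosomes = 80L,
                        grid_points = pool_chromosomes + 1L,
                        details = FALSE) {
    if (error_rate >= 0.5 || error_rate < 0)
        stop("error_rate must lie in [0, 0.5)")
    stopifnot(pool_chromosomes >= 2L, grid_points >= 3L)
    th <- if (inherits(theta, "ThetaEstimate")) theta$theta else theta
    f <- seq(0, 1, length.out = grid_points)
    a_n <- harmonicNumber(pool_chromosomes - 1L)
    w <- numeric(grid_points)
    interior <- seq(2L, grid_points - 1L)
    w[interior] <- th * (1 / f[interior] + 1 / (1 - f[interior]))
    mass_int <- min(1, th * a_n)
    prior <- numeric(grid_points)
    if (sum(w) > 0)
        prior[interior] <- w[interior] / sum(w) * mass_int
    prior[c(1L, grid_points)] <- (1 - sum(prior[interior])) / 2
    e <- error_rate
    q <- f * (1 - e) + (1 - f) * e
    n <- ref + alt
    out <- data.frame(aaf_estimate = rep(NA_real_, length(n)),
                      p0 = NA_real_, p1 = NA_real_, depth = n)
    ok <- which(!is.na(n) & n >= 1)
    if (length(ok)) {
        ## log posterior, row-normalized for numerical stability
        lp <- outer(alt[ok], log(q)) + outer(ref[ok], log1p(-q)) +
            rep(log(prior), each = length(ok))
        lp <- lp - apply(lp, 1L, max)
        post <- exp(lp)
        post <- post / rowSums(post)
        out$aaf_estimate[ok] <- as.numeric(post %*% f)
        out$p0[ok] <- post[, 1L]
        out$p1[ok] <- post[, grid_points]
        if (details) {
            full <- matrix(NA_real_, length(n), grid_points)
            full[ok, ] <- post
            attr(out, "grid") <- f
            attr(out, "posterior") <- full
        }
    }
    out
}

#' Posterior fixation rules
#'
#' Snaps estimated frequencies to the boundaries from the posterior masses:
#' the frequency is set to 0 whenever `1 - p0 < 0.9` (i.e. the posterior
#' probability of any non-reference frequency falls below 0.9), else to 1
#' when `p1 > 0.9`, else the posterior-mean estimate is kept. The zero rule
#' is evaluated first.
#'
#' @param post a [posteriorAF()] data.frame.
#' @param threshold posterior mass threshold (default 0.9).
#' @return numeric vector of frequencies in `[0, 1]` (`NA` where the
#'   posterior is undefined).
#' @export
applyFixationRules <- function(post, threshold = 0.9) {
    aaf <- post$aaf_estimate
    zero <- !is.na(post$p0) & (1 - post$p0) < threshold
    one <- !zero & !is.na(post$p1) & post$p1 > threshold
    aaf[zero] <- 0
    aaf[one] <- 1
    aaf
}

#' Estimate an AAF matrix from pooled counts
#'
#' Runs [estimateTheta()] and [posteriorAF()] sample by sample and applies
#' the fixation rules, producing the AAF_pool matrix for the downstream
#' analyses. Cells with zero depth are missing.
#'
#' @inheritParams estimateTheta
#' @inheritParams posteriorAF
#' @param fixation apply [applyFixationRules()] (default TRUE).
#' @param theta optional fixed theta used for every sample instead of the
#'   per-sample estimate.
#' @return a [PoolAAF] with assays `aaf`, `p0`, `p1`; per-sample thetas in
#'   `metadata(x)$theta`.
#' @export
estimateAAF <- function(counts, n_plants = 40L, error_rate = 0.001,
                        mac = 3L, min_depth = 30L, theta = NULL,
                        fixation = TRUE,
                        grid_points = 2L * n_plants + 1L) {
    samples <- colnames(counts)
    n <- nrow(counts)
    aaf <- p0 <- p1 <- matrix(NA_real_, n, length(samples),
                              dimnames = list(rownames(counts), samples))
    thetas <- setNames(numeric(length(samples)), samples)
    for (s in samples) {
        th <- if (is.null(theta))
            estimateTheta(counts, s, mac = mac, min_depth = min_depth,
                          n_plants = n_plants)$theta
        else theta
        thetas[s] <- th
        post <- posteriorAF(refCounts(counts)[, s], altCounts(counts)[, s],
                            theta = th, error_rate = error_rate,
                            pool_chromosomes = 2L * n_plants,
                            grid_points = grid_points)
        aaf[, s] <- if (fixation) applyFixationRules(post)
                    else post$aaf_estimate
        p0[, s] <- post$p0
        p1[, s] <- post$p1
    }
    out <- PoolAAF(rowRanges(counts), aaf = aaf, design = colData(counts),
                   p0 = p0, p1 = p1)
    metadata(out)$theta <- thetas
    out
}

#' Allele frequency from individual genotype calls
#'
#' `AAF_ind`: the summed alternative-allele dose (hom ref 0, het 1, hom alt
#' 2) divided by the number of chromosomes actually genotyped; missing
#' calls are excluded from numerator and denominator.
#'
#' @param gt a [GenotypeCalls] object.
#' @return named numeric vector, one AAF per locus (`NA` where every call
#'   is missing).
#' @export
#' @examples
#' # 25 hom ref, 10 het, 5 hom alt -> (10 + 10) / 80 = 0.25
aafFromGenotypes <- function(gt) {
    g <- genoCalls(gt)
    called <- rowSums(!is.na(g))
    out <- rowSums(g, na.rm = TRUE) / (2 * called)
    out[called == 0L] <- NA_real_
    out
}
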