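## Pool-versus-individual validation metrics: allele-frequency agreement,
## genotype-call concordance across technical replicates, SNP-set overlap,
## and the allele-frequency spectra of reproducible vs non-reproducible
## SNP calls.

#' Agreement between two allele-frequency vectors
#'
#' Pearson correlation and median deviation between paired AAF estimates
#' (e.g. AAF_ind from individual genotyping against AAF_pool from a pooled
#' library), over loci with both values present. The median deviation is
#' the median absolute difference; the signed median difference is reported
#' alongside for transparency.
#'
#' @param x,y numeric vectors of allele frequencies (matched loci; `NA`
#'   pairs are dropped).
#' @return list of class `AgreementSummary`: `n_snps`, `pearson_r`,
#'   `median_deviation`, `median_signed`.
#' @export
compareAAF <- function(x, y) {
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 3L)
        stop("need at least 3 paired non-missing loci, got ", sum(ok))
    d <- x[ok] - y[ok]
    out <- list(n_snps = sum(ok), pearson_r = cor(x[ok], y[ok]),
                median_deviation = median(abs(d)),
                median_signed = median(d))
    class(out) <- "AgreementSummary"
    out
}

#' @export
print.AgreementSummary <- function(x, ...) {
    cat("AAF agreement over", x$n_snps, "SNPs: r =",
        signif(x$pearson_r, 3), ", median |deviation| =",
        signif(x$median_deviation, 3), "\n")
    invisible(x)
}

#' Genotype-call concordance across technical replicates
#'
#' Fraction of identical genotype calls among replicate GBS libraries of
#' the same individual. Loci are intersected across replicates; by default
#' only loci called (non-missing) in every replicate enter the
#' denominator, with `denominator = "union"` using loci called in both
#' members of each pairwise comparison.
#'
#' @param replicates list of two or more [GenotypeCalls] objects for the
#'   same individual (one column each, or matching columns).
#' @param denominator `"complete"` (default) or `"union"`.
#' @return list: `pairwise` (named vector of pairwise identical fractions),
#'   `mean_pairwise`, `all_way` (fraction identical across all
#'   replicates), `n_loci`.
#' @export
genotypeConcordance <- function(replicates,
                                denominator = c("complete", "union")) {
    denominator <- match.arg(denominator)
    stopifnot(length(replicates) >= 2L)
    keys <- Reduce(intersect, lapply(replicates, rownames))
    if (length(keys) == 0L)
        stop("replicates share no loci")
    g <- vapply(replicates, function(x) genoCalls(x)[keys, 1L],
                numeric(length(keys)))
    complete <- rowSums(is.na(g)) == 0L
    pairs <- utils::combn(ncol(g), 2L)
    pw <- apply(pairs, 2L, function(p) {
        ok <- if (denominator == "complete") complete
              else !is.na(g[, p[1]]) & !is.na(g[, p[2]])
        mean(g[ok, p[1]] == g[ok, p[2]])
    })
    names(pw) <- apply(pairs, 2L, paste, collapse = "-")
    allway <- mean(apply(g[complete, , drop = FALSE], 1L,
                         function(r) length(unique(r)) == 1L))
    list(pairwise = pw, mean_pairwise = mean(pw), all_way = allway,
         n_loci = sum(complete))
}

#' SNP-set intersections (Venn cells)
#'
#' Exact cell counts of the Venn partition of two or more named SNP sets,
#' with percentages relative to the union. For three sets this reproduces
#' the reproducibility summary of replicate pools (SNPs unique to one pool,
#' shared by two, common to all three).
#'
#' @param sets named list of vectors (locus keys or indices).
#' @return data.frame with columns `cell` (membership pattern such as
#'   `"A"`, `"A&B"`), `count`, `pct_of_union`.
#' @export
snpSetIntersections <- function(sets) {
    stopifnot(length(sets) >= 2L, !is.null(names(sets)))
    u <- unique(unlist(sets))
    memb <- vapply(sets, function(s) u %in% s, logical(length(u)))
    if (length(u) == 1L) memb <- matrix(memb, nrow = 1L,
                                        dimnames = list(NULL, names(sets)))
    pattern <- apply(memb, 1L, function(r)
        paste(names(sets)[r], collapse = "&"))
    ## all non-empty membership patterns, in a stable order
    combos <- unlist(lapply(seq_along(sets), function(k)
        utils::combn(names(sets), k, paste, collapse = "&",
                     simplify = FALSE)))
    counts <- vapply(combos, function(cb) sum(pattern == cb), integer(1))
    data.frame(cell = unlist(combos), count = counts,
               pct_of_union = 100 * counts / max(1L, length(u)),
               row.names = NULL, stringsAsFactors = FALSE)
}

#' AAF spectrum of reproducible vs non-reproducible SNPs
#'
#' Fraction of SNPs with AAF below a cutoff in each class. Non-reproducible
#' SNP calls (called in one replicate pool but not the other) are expected
#' to pile up below a few percent AAF, the signature of sequencing-error
#' calls.
#'
#' @param aaf named numeric vector of AAF values in the focal sample.
#' @param reproducible,nonreproducible disjoint vectors of locus keys.
#' @param cutoff AAF cutoff (default 0.03).
#' @return list: `reproducible`, `nonreproducible` (fractions below the
#'   cutoff, `NA` with a warning for an empty class), `cutoff`.
#' @export
spectrumByReproducibility <- function(aaf, reproducible, nonreproducible,
                                      cutoff = 0.03) {
    if (length(intersect(reproducible, nonreproducible)))
        stop("reproducible and non-reproducible sets must be disjoint")
    frac <- function(keys, label) {
        v <- aaf[as.character(keys)]
        v <- v[!is.na(v)]
        if (length(v) == 0L) {
            warning("no ", label, " SNPs with AAF values")
            return(NA_real_)
        }
        mean(v < cutoff)
    }
    list(reproducible = frac(reproducible, "reproducible"),
         nonreproducible = frac(nonreproducible, "non-reproducible"),
         cutoff = cutoff)
}
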