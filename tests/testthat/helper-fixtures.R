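## Fixtures built in code; no binary files.

## small count matrix with full control over the cells
makeCounts <- function(ref, alt, extra = NULL, samples = NULL,
                       chrom = "chr1") {
    ref <- as.matrix(ref); alt <- as.matrix(alt)
    if (is.null(samples)) samples <- paste0("s", seq_len(ncol(ref)))
    dimnames(ref) <- dimnames(alt) <- list(NULL, samples)
    if (!is.null(extra)) {
        extra <- as.matrix(extra); dimnames(extra) <- dimnames(ref)
    }
    loci <- snpLoci(rep(chrom, nrow(ref)), seq_len(nrow(ref)) * 10L,
                    rep("A", nrow(ref)), rep("G", nrow(ref)))
    PoolCounts(loci, ref = ref, alt = alt, extra = extra)
}

makeAAF <- function(m, samples = NULL, design = NULL, chrom = "chr1") {
    m <- as.matrix(m)
    if (is.null(samples)) samples <- paste0("s", seq_len(ncol(m)))
    colnames(m) <- samples
    loci <- snpLoci(rep(chrom, nrow(m)), seq_len(nrow(m)) * 10L,
                    rep("A", nrow(m)), rep("G", nrow(m)))
    PoolAAF(loci, aaf = m, design = design)
}

makeGenotypes <- function(g, individuals = NULL, chrom = "chr1") {
    g <- as.matrix(g)
    if (is.null(individuals))
        individuals <- paste0("p", seq_len(ncol(g)))
    colnames(g) <- individuals
    loci <- snpLoci(rep(chrom, nrow(g)), seq_len(nrow(g)) * 10L,
                    rep("A", nrow(g)), rep("G", nrow(g)))
    GenotypeCalls(loci, geno = g)
}

## plain-text VCF writer for reader tests: records is a data.frame with
## chrom, pos, ref, alt and one column per sample holding GT:DP:GQ:AD
writeToyVcf <- function(records, samples, path) {
    hdr <- c("##fileformat=VCFv4.2",
             paste0("##FORMAT=<ID=GT,Number=1,Type=String,",
                    "Description=\"Genotype\">"),
             paste0("##FORMAT=<ID=DP,Number=1,Type=Integer,",
                    "Description=\"Read depth\">"),
             paste0("##FORMAT=<ID=GQ,Number=1,Type=Integer,",
                    "Description=\"Genotype quality\">"),
             paste0("##FORMAT=<ID=AD,Number=R,Type=Integer,",
                    "Description=\"Allelic depths\">"),
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                     "FILTER", "INFO", "FORMAT", samples),
                   collapse = "\t"))
    body <- apply(records, 1L, function(r)
        paste(c(r[["chrom"]], r[["pos"]], ".", r[["ref"]], r[["alt"]],
                ".", "PASS", ".", "GT:DP:GQ:AD",
                unlist(r[samples])), collapse = "\t"))
    writeLines(c(hdr, body), path)
    path
}

## independent brute-force grid posterior (linear space, no shortcuts);
## oracle for posteriorAF
bruteForcePosterior <- function(ref, alt, theta, e, C) {
    f <- (0:C) / C
    a_n <- sum(1 / seq_len(C - 1))
    w <- rep(0, C + 1)
    for (k in 2:C) w[k] <- theta * (1 / f[k] + 1 / (1 - f[k]))
    prior <- rep(0, C + 1)
    prior[2:C] <- w[2:C] / sum(w) * min(1, theta * a_n)
    prior[c(1, C + 1)] <- (1 - sum(prior[2:C])) / 2
    q <- f * (1 - e) + (1 - f) * e
    lik <- vapply(q, function(qq) dbinom(alt, ref + alt, qq), numeric(1))
    post <- prior * lik
    post <- post / sum(post)
    list(mean = sum(post * f), p0 = post[1], p1 = post[C + 1], post = post)
}
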