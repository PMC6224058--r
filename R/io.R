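#' @importFrom VariantAnnotation readVcf geno ScanVcfParam
#' @importFrom SummarizedExperiment rowRanges
NULL

## ---------------------------------------------------------------------------
## allele-count tables
## ---------------------------------------------------------------------------

#' Read and write allelic read-count tables
#'
#' The TSV dialect has header `chrom  pos  ref  alt` followed by paired
#' per-sample columns `<sample>_ref`, `<sample>_alt` and optionally
#' `<sample>_extra` (reads supporting a third or fourth allele). Missing
#' counts are written as `.`. The `vcf-ad` dialect reads allelic depths from
#' the `AD` genotype field of a VCF; the first AD entry is the reference
#' count, the second the alternative count, and any further entries are
#' summed into `extra`. Only biallelic single-nucleotide records are kept.
#'
#' Loci are returned in the deterministic order (chromosome lexicographic,
#' then position) regardless of file order, so `writeCountTable()` followed
#' by `readCountTable()` is an exact roundtrip.
#'
#' @param path input file path.
#' @param dialect `"tsv"` or `"vcf-ad"`.
#' @return a [PoolCounts] object.
#' @export
readCountTable <- function(path, dialect = c("tsv", "vcf-ad")) {
    dialect <- match.arg(dialect)
    if (dialect == "vcf-ad")
        return(.readCountsVcfAD(path))
    tab <- read.delim(path, stringsAsFactors = FALSE, na.strings = ".",
                      check.names = FALSE)
    need <- c("chrom", "pos", "ref", "alt")
    if (!all(need %in% names(tab)))
        stop("count table must start with header columns ",
             paste(need, collapse = ", "))
    cnt <- tab[setdiff(names(tab), need)]
    is_ref <- grepl("_ref$", names(cnt))
    is_alt <- grepl("_alt$", names(cnt))
    is_ext <- grepl("_extra$", names(cnt))
    samples <- sub("_ref$", "", names(cnt)[is_ref])
    if (!setequal(sub("_alt$", "", names(cnt)[is_alt]), samples))
        stop("per-sample _ref/_alt column pairs do not match")
    bad <- which(!vapply(cnt, is.numeric, logical(1)))
    if (length(bad)) {
        rows <- which(is.na(suppressWarnings(
            as.numeric(cnt[[bad[1]]]))) & !is.na(cnt[[bad[1]]]))
        stop("unparseable counts in column '", names(cnt)[bad[1]],
             "', data row(s) ", paste(head(rows, 5), collapse = ", "))
    }
    neg <- which(rowSums(cnt < 0, na.rm = TRUE) > 0)
    if (length(neg))
        stop("negative count in data row(s) ",
             paste(head(neg, 5), collapse = ", "))
    grab <- function(suffix) {
        cols <- paste0(samples, suffix)
        m <- matrix(NA_integer_, nrow(tab), length(samples),
                    dimnames = list(NULL, samples))
        for (j in seq_along(cols))
            if (cols[j] %in% names(cnt))
                m[, j] <- as.integer(cnt[[cols[j]]])
        m
    }
    extra <- grab("_extra")
    extra[is.na(extra)] <- 0L
    PoolCounts(snpLoci(tab$chrom, tab$pos, tab$ref, tab$alt),
               ref = grab("_ref"), alt = grab("_alt"), extra = extra)
}

#' @param counts a [PoolCounts] object.
#' @rdname readCountTable
#' @export
writeCountTable <- function(counts, path) {
    loci <- rowRanges(counts)
    out <- data.frame(chrom = as.character(seqnames(loci)),
                      pos = start(loci), ref = mcols(loci)$ref,
                      alt = mcols(loci)$alt, check.names = FALSE)
    for (s in colnames(counts)) {
        out[[paste0(s, "_ref")]] <- refCounts(counts)[, s]
        out[[paste0(s, "_alt")]] <- altCounts(counts)[, s]
        out[[paste0(s, "_extra")]] <- extraCounts(counts)[, s]
    }
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                na = ".")
    invisible(path)
}

.readCountsVcfAD <- function(path) {
    vcf <- readVcf(path)
    ad <- geno(vcf)$AD
    if (is.null(ad))
        stop("VCF has no AD (allelic depth) genotype field")
    keep <- .biallelicSnvs(vcf)
    rr <- rowRanges(vcf)[keep]
    ad <- ad[keep, , drop = FALSE]
    n <- length(rr); s <- colnames(ad)
    ref <- alt <- matrix(NA_integer_, n, length(s), dimnames = list(NULL, s))
    extra <- matrix(0L, n, length(s), dimnames = list(NULL, s))
    for (j in seq_along(s)) for (i in seq_len(n)) {
        v <- ad[[i, j]]
        if (length(v) >= 2 && !all(is.na(v))) {
            ref[i, j] <- as.integer(v[1])
            alt[i, j] <- as.integer(v[2])
            if (length(v) > 2)
                extra[i, j] <- as.integer(sum(v[-(1:2)], na.rm = TRUE))
        }
    }
    PoolCounts(snpLoci(as.character(seqnames(rr)), start(rr),
                       as.character(rr$REF),
                       vapply(rr$ALT, function(a) as.character(a[1]),
                              character(1))),
               ref = ref, alt = alt, extra = extra)
}

.biallelicSnvs <- function(vcf) {
    rr <- rowRanges(vcf)
    nalt <- lengths(rr$ALT)
    keep <- nalt == 1L & nchar(as.character(rr$REF)) == 1L
    altc <- rep(NA_character_, length(rr))
    altc[keep] <- vapply(rr$ALT[keep], function(a) as.character(a[1]),
                         character(1))
    keep <- keep & !is.na(altc) & nchar(altc) == 1L & altc %in%
        c("A", "C", "G", "T")
    dropped <- sum(!keep)
    if (dropped > 0)
        message(dropped, " indel/multi-allelic record(s) removed")
    keep
}

## ---------------------------------------------------------------------------
## AAF tables
## ---------------------------------------------------------------------------

#' Read and write alternative-allele-frequency tables
#'
#' Header `chrom  pos  ref  alt` followed by one numeric column per sample;
#' `.` encodes a missing estimate.
#'
#' @param path file path.
#' @return a [PoolAAF] object.
#' @export
readAAFTable <- function(path) {
    tab <- read.delim(path, stringsAsFactors = FALSE, na.strings = ".",
                      check.names = FALSE)
    need <- c("chrom", "pos", "ref", "alt")
    if (!all(need %in% names(tab)))
        stop("AAF table must start with header columns ",
             paste(need, collapse = ", "))
    m <- as.matrix(tab[setdiff(names(tab), need)])
    storage.mode(m) <- "double"
    PoolAAF(snpLoci(tab$chrom, tab$pos, tab$ref, tab$alt), aaf = m)
}

#' @param aaf a [PoolAAF] object.
#' @rdname readAAFTable
#' @export
writeAAFTable <- function(aaf, path) {
    loci <- rowRanges(aaf)
    out <- cbind(data.frame(chrom = as.character(seqnames(loci)),
                            pos = start(loci), ref = mcols(loci)$ref,
                            alt = mcols(loci)$alt),
                 as.data.frame(aafValues(aaf)))
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                na = ".")
    invisible(path)
}

## ---------------------------------------------------------------------------
## genotype VCF
## ---------------------------------------------------------------------------

#' Read individual genotype calls from a VCF
#'
#' Keeps biallelic single-nucleotide records only (indels and multi-allelic
#' records are dropped and their number reported). Genotypes are converted
#' to alternative-allele doses (0/1/2); calls with read depth below
#' `min_depth` or genotype quality below `min_gq` are flagged as missing,
#' matching the RD >= 10 / GQ >= 30 thresholds used for individual-plant
#' GBS genotyping.
#'
#' @param path VCF file (plain text or bgzip).
#' @param min_depth minimum per-call read depth (default 10).
#' @param min_gq minimum genotype quality (default 30).
#' @return a [GenotypeCalls] object with assays `geno`, and `depth`/`gq`
#'   when the fields are present.
#' @export
readGenotypeVcf <- function(path, min_depth = 10L, min_gq = 30L) {
    vcf <- readVcf(path)
    gt <- geno(vcf)$GT
    if (is.null(gt))
        stop("VCF has no GT genotype field")
    keep <- .biallelicSnvs(vcf)
    rr <- rowRanges(vcf)[keep]
    gt <- gt[keep, , drop = FALSE]
    dose <- matrix(NA_real_, nrow(gt), ncol(gt),
                   dimnames = dimnames(gt))
    gsub1 <- gsub("\\|", "/", gt)
    dose[gsub1 %in% c("0/0")] <- 0
    dose[gsub1 %in% c("0/1", "1/0")] <- 1
    dose[gsub1 %in% c("1/1")] <- 2
    dp <- geno(vcf)$DP; gq <- geno(vcf)$GQ
    if (!is.null(dp)) {
        dp <- dp[keep, , drop = FALSE]
        dose[!is.na(dp) & dp < min_depth] <- NA
        dose[is.na(dp)] <- NA
    } else warning("no DP field: depth threshold not applied")
    if (!is.null(gq)) {
        gq <- gq[keep, , drop = FALSE]
        dose[!is.na(gq) & gq < min_gq] <- NA
    } else warning("no GQ field: genotype-quality threshold not applied")
    GenotypeCalls(snpLoci(as.character(seqnames(rr)), start(rr),
                          as.character(rr$REF),
                          vapply(rr$ALT, function(a) as.character(a[1]),
                                 character(1))),
                  geno = dose, depth = dp, gq = gq)
}
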