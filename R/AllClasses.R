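#' @importClassesFrom SummarizedExperiment RangedSummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assayNames rowRanges colData
#' @importFrom S4Vectors DataFrame mcols metadata 'metadata<-'
#' @importFrom GenomicRanges GRanges seqnames start
#' @importFrom IRanges IRanges
NULL

## ---------------------------------------------------------------------------
## Loci
## ---------------------------------------------------------------------------

#' Build a GRanges of biallelic SNP loci
#'
#' Loci are single-base positions (1-based, VCF convention) carrying a
#' reference and an alternative allele in their metadata columns. Input
#' order is preserved here; the container constructors ([PoolCounts()] and
#' friends) impose the package's deterministic ordering — chromosome names
#' lexicographically (C locale), then position ascending — on loci and assay
#' rows together, so matrices read from differently ordered files are
#' directly comparable.
#'
#' @param chrom character vector of chromosome/scaffold names.
#' @param pos integer vector of 1-based positions.
#' @param ref,alt single-base reference and alternative alleles.
#' @return a [GenomicRanges::GRanges] with mcols `ref` and `alt` and names
#'   `"chrom:pos"`.
#' @export
#' @examples
#' snpLoci(c("chr2", "chr1"), c(5L, 10L), c("A", "C"), c("G", "T"))
snpLoci <- function(chrom, pos, ref, alt) {
    chrom <- as.character(chrom)
    pos <- as.integer(pos)
    if (any(is.na(pos)) || any(pos < 1L))
        stop("locus positions must be integers >= 1")
    if (any(ref == alt))
        stop("ref and alt allele must differ at every locus")
    key <- paste0(chrom, ":", pos)
    if (anyDuplicated(key))
        stop("duplicate (chrom, pos) keys: ",
             paste(unique(key[duplicated(key)]), collapse = ", "))
    gr <- GRanges(chrom, IRanges(pos, width = 1L),
                  ref = as.character(ref), alt = as.character(alt))
    names(gr) <- key
    gr
}

## deterministic locus order: chromosome lexicographic (C locale), then pos
orderLoci <- function(chrom, pos) {
    old <- Sys.getlocale("LC_COLLATE")
    on.exit(suppressWarnings(Sys.setlocale("LC_COLLATE", old)), add = TRUE)
    suppressWarnings(Sys.setlocale("LC_COLLATE", "C"))
    order(chrom, pos)
}

lociKeys <- function(gr) names(gr)

## ---------------------------------------------------------------------------
## PoolCounts
## ---------------------------------------------------------------------------

#' Container classes for pool-GBS data
#'
#' Three `RangedSummarizedExperiment` subclasses hold the data flowing
#' through the pipeline:
#' \describe{
#'   \item{`PoolCounts`}{per-locus, per-sample allelic read counts, assays
#'     `ref`, `alt`, `extra` (reads supporting neither declared allele;
#'     used by the multi-allelic filter).}
#'   \item{`PoolAAF`}{per-locus, per-sample alternative-allele frequencies in
#'     `[0, 1]`, assay `aaf`, `NA` encoding missing estimates. Estimators may
#'     attach `p0`/`p1` assays with the posterior fixation probabilities.}
#'   \item{`GenotypeCalls`}{per-locus, per-individual genotype doses over
#'     \{0 = hom ref, 1 = het, 2 = hom alt, `NA` = missing\}, assay `geno`,
#'     optionally `depth` and `gq`.}
#' }
#' Rows are the loci (a [snpLoci()] `GRanges`), columns the samples; the
#' sample design table (see [trialDesign()]) lives in `colData`.
#'
#' @name PoolCounts-class
#' @aliases PoolCounts-class PoolAAF-class GenotypeCalls-class
#' @exportClass PoolCounts PoolAAF GenotypeCalls
setClass("PoolCounts", contains = "RangedSummarizedExperiment")

setValidity("PoolCounts", function(object) {
    need <- c("ref", "alt", "extra")
    if (!all(need %in% assayNames(object)))
        return(paste("assays must include", paste(need, collapse = ", ")))
    for (a in need) {
        m <- assay(object, a)
        if (any(m < 0, na.rm = TRUE))
            return(paste("negative counts in assay", a))
    }
    if (anyDuplicated(names(rowRanges(object))))
        return("duplicate (chrom, pos) locus keys")
    TRUE
})

setClass("PoolAAF", contains = "RangedSummarizedExperiment")

setValidity("PoolAAF", function(object) {
    if (!"aaf" %in% assayNames(object))
        return("assay 'aaf' is required")
    m <- assay(object, "aaf")
    if (any(m < 0 | m > 1, na.rm = TRUE))
        return("non-missing AAF values must lie in [0, 1]")
    TRUE
})

setClass("GenotypeCalls", contains = "RangedSummarizedExperiment")

setValidity("GenotypeCalls", function(object) {
    if (!"geno" %in% assayNames(object))
        return("assay 'geno' is required")
    g <- assay(object, "geno")
    ok <- is.na(g) | g %in% c(0, 1, 2)
    if (!all(ok))
        return("genotype calls must be 0, 1, 2 or NA")
    TRUE
})

#' @param loci a `GRanges` from [snpLoci()].
#' @param ref,alt,extra non-negative integer matrices, loci x samples.
#'   `extra` defaults to all-zero.
#' @param design optional per-sample `data.frame`/`DataFrame` stored as
#'   `colData` (see [trialDesign()]); row order must match the columns.
#' @return a validated object of the corresponding class, rows sorted in the
#'   deterministic locus order.
#' @rdname PoolCounts-class
#' @export
PoolCounts <- function(loci, ref, alt, extra = NULL, design = NULL) {
    ref <- as.matrix(ref); alt <- as.matrix(alt)
    if (is.null(extra))
        extra <- matrix(0L, nrow(ref), ncol(ref), dimnames = dimnames(ref))
    extra <- as.matrix(extra)
    .newRSE("PoolCounts", loci, list(ref = ref, alt = alt, extra = extra),
            design)
}

#' @param aaf numeric matrix in `[0, 1]` with `NA` for missing.
#' @rdname PoolCounts-class
#' @export
PoolAAF <- function(loci, aaf, design = NULL, ...) {
    .newRSE("PoolAAF", loci, c(list(aaf = as.matrix(aaf)), list(...)), design)
}

#' @param geno genotype-dose matrix over \{0, 1, 2, `NA`\}.
#' @param depth,gq optional read-depth and genotype-quality matrices.
#' @param ... further assays (e.g. posterior fixation probabilities).
#' @rdname PoolCounts-class
#' @export
GenotypeCalls <- function(loci, geno, depth = NULL, gq = NULL, design = NULL) {
    assays <- list(geno = as.matrix(geno))
    if (!is.null(depth)) assays$depth <- as.matrix(depth)
    if (!is.null(gq)) assays$gq <- as.matrix(gq)
    .newRSE("GenotypeCalls", loci, assays, design)
}

.newRSE <- function(class, loci, assays, design) {
    n <- length(loci)
    for (a in names(assays))
        if (nrow(assays[[a]]) != n)
            stop("assay '", a, "' has ", nrow(assays[[a]]),
                 " rows but there are ", n, " loci")
    ## impose the deterministic locus order on the assays via the keys
    o <- orderLoci(as.character(seqnames(loci)), start(loci))
    loci <- loci[o]
    assays <- lapply(assays, function(m) {
        m <- m[o, , drop = FALSE]
        rownames(m) <- names(loci)
        m
    })
    cd <- if (is.null(design)) NULL else DataFrame(design)
    se <- if (is.null(cd))
        SummarizedExperiment(assays = assays, rowRanges = loci)
    else
        SummarizedExperiment(assays = assays, rowRanges = loci, colData = cd)
    new(class, se)
}

## ---------------------------------------------------------------------------
## accessors and show
## ---------------------------------------------------------------------------

#' @rdname pool-accessors
setMethod("refCounts", "PoolCounts", function(x) assay(x, "ref"))
#' @rdname pool-accessors
setMethod("altCounts", "PoolCounts", function(x) assay(x, "alt"))
#' @rdname pool-accessors
setMethod("extraCounts", "PoolCounts", function(x) assay(x, "extra"))
#' @rdname pool-accessors
setMethod("aafValues", "PoolAAF", function(x) assay(x, "aaf"))
#' @rdname pool-accessors
setMethod("genoCalls", "GenotypeCalls", function(x) assay(x, "geno"))

setMethod("show", "PoolCounts", function(object) {
    cat("PoolCounts: ", nrow(object), " loci x ", ncol(object),
        " samples\n", sep = "")
    d <- refCounts(object) + altCounts(object)
    cat("  median total depth: ", stats::median(d), "\n", sep = "")
    callNextMethod()
})

setMethod("show", "PoolAAF", function(object) {
    m <- aafValues(object)
    cat("PoolAAF: ", nrow(object), " loci x ", ncol(object), " samples (",
        sum(is.na(m)), " missing cells)\n", sep = "")
    callNextMethod()
})

setMethod("show", "GenotypeCalls", function(object) {
    g <- genoCalls(object)
    cat("GenotypeCalls: ", nrow(object), " loci x ", ncol(object),
        " individuals (", round(100 * mean(is.na(g)), 1),
        "% missing)\n", sep = "")
    callNextMethod()
})

#' Tiny example count matrix
#'
#' Two loci, three samples; used in documentation examples.
#' @return a [PoolCounts] object.
#' @export
toyCounts <- function() {
    loci <- snpLoci(c("chr1", "chr1"), c(100L, 200L), c("A", "G"), c("T", "C"))
    s <- c("s1", "s2", "s3")
    PoolCounts(loci,
               ref = matrix(c(30L, 40L, 25L, 35L, 45L, 20L), 2,
                            dimnames = list(NULL, s)),
               alt = matrix(c(10L, 0L, 15L, 5L, 1L, 22L), 2,
                            dimnames = list(NULL, s)))
}
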