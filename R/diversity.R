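## Diversity dynamics of the ryegrass component: expected heterozygosity
## time series with its sequential ANOVA, centred unscaled PCA of the AAF
## matrix, cultivar-private SNP detection and cultivar-abundance tracking.

#' Expected heterozygosity per locus and sample
#'
#' `He = 2 * AAF * (1 - AAF)` per locus and sample, and its per-sample mean
#' over non-missing loci (mean He), the diversity index tracked through
#' time. He is symmetric in the two alleles and maximal (0.5) at AAF 0.5.
#'
#' @param aaf a [PoolAAF] object or a numeric matrix of allele frequencies.
#' @return list of class `DiversityTable`: `he` (loci x samples matrix) and
#'   `mean_he` (named per-sample vector).
#' @export
#' @examples
#' heterozygosity(matrix(c(0.5, 0.25), 2, 1))$he  # 0.5, 0.375
heterozygosity <- function(aaf) {
    m <- if (is(aaf, "PoolAAF")) aafValues(aaf) else as.matrix(aaf)
    he <- 2 * m * (1 - m)
    out <- list(he = he, mean_he = colMeans(he, na.rm = TRUE))
    class(out) <- "DiversityTable"
    out
}

#' Sequential ANOVA of mean He over the trial design
#'
#' Fits `mean_He ~ S + S:R + S:Y` (seed composition, its interaction with
#' replicate, and its interaction with year) by sequential least squares
#' and returns the Type-I ANOVA table. The `S:Y` term captures temporal
#' diversity changes consistent across replicate plots; plot-specific
#' changes end up in the residual. On the full 7 x 2 x 4 design the
#' degrees of freedom are 6, 7, 21 and 21 (residual), total 55.
#'
#' @param mean_he named per-sample vector (from [heterozygosity()]) or a
#'   `DiversityTable`.
#' @param design design table with rows matching the samples.
#' @return data.frame with per-term `df`, `sum_sq`, `mean_sq`, `statistic`
#'   (F), `p_value`; rows `S`, `S:R`, `S:Y`, `Residuals`.
#' @export
anovaMeanHe <- function(mean_he, design) {
    if (inherits(mean_he, "DiversityTable")) mean_he <- mean_he$mean_he
    stopifnot(length(mean_he) == nrow(design))
    dat <- data.frame(y = as.numeric(mean_he),
                      S = factor(design$composition),
                      R = factor(design$replicate),
                      Y = factor(design$year))
    fit <- aov(y ~ S + S:R + S:Y, data = dat)
    tab <- summary(fit)[[1L]]
    qrr <- qr(model.matrix(fit))
    if (qrr$rank < ncol(model.matrix(fit)))
        stop("rank-deficient design: a term is confounded ",
             "(aliased columns in S:R or S:Y)")
    data.frame(term = trimws(rownames(tab)), df = as.integer(tab[["Df"]]),
               sum_sq = tab[["Sum Sq"]], mean_sq = tab[["Mean Sq"]],
               statistic = tab[["F value"]], p_value = tab[["Pr(>F)"]],
               row.names = NULL, stringsAsFactors = FALSE)
}

#' Centred, non-scaled PCA of the AAF matrix
#'
#' Samples are rows and SNPs columns; columns are centred but not scaled,
#' so SNPs contribute in proportion to their allele-frequency variance.
#' The first component separates the two ryegrass cultivars and its score
#' is the `PC1` covariate of the selection-scan model. For
#' reproducibility, the sign of PC1 is fixed so that pure-Merks samples
#' (compositions 1 and 3) score negative on average; without such samples
#' the largest-magnitude loading is made positive.
#'
#' @param aaf a [PoolAAF] (complete, post-filter) or numeric matrix
#'   (loci x samples).
#' @param design optional design table used for the sign convention; taken
#'   from `colData(aaf)` when available.
#' @return list of class `PcaResult`: `scores` (samples x components),
#'   `variance_explained`, `sdev`, `n_components`.
#' @export
pcaAAF <- function(aaf, design = NULL) {
    m <- if (is(aaf, "PoolAAF")) aafValues(aaf) else as.matrix(aaf)
    if (anyNA(m))
        stop("AAF matrix contains missing values; run filterCascade first")
    if (ncol(m) < 2L)
        stop("need at least 2 samples")
    if (is.null(design) && is(aaf, "PoolAAF") && ncol(colData(aaf)) > 0L)
        design <- as.data.frame(colData(aaf))
    pc <- prcomp(t(m), center = TRUE, scale. = FALSE)
    scores <- pc$x
    ve <- pc$sdev^2 / sum(pc$sdev^2)
    flip <- FALSE
    if (!is.null(design) && any(design$ryegrass_content == "Merks")) {
        pure <- design$ryegrass_content == "Merks"
        flip <- mean(scores[pure, 1L]) > 0
    } else {
        flip <- pc$rotation[which.max(abs(pc$rotation[, 1L])), 1L] < 0
    }
    if (flip) {
        scores[, 1L] <- -scores[, 1L]
        pc$rotation[, 1L] <- -pc$rotation[, 1L]
    }
    out <- list(scores = scores, variance_explained = ve, sdev = pc$sdev,
                rotation = pc$rotation, n_components = ncol(scores))
    class(out) <- "PcaResult"
    out
}

#' @export
print.PcaResult <- function(x, ...) {
    cat("PCA of AAF matrix:", nrow(x$scores), "samples,",
        x$n_components, "components; PC1 explains",
        sprintf("%.1f%%", 100 * x$variance_explained[1L]), "\n")
    invisible(x)
}

#' Cultivar-private SNP detection
#'
#' A locus is private to the focal cultivar when its (post-fixation) AAF is
#' 0 in every sample of plots sown only with the other cultivar, and
#' positive in at least one sample of a plot containing the focal cultivar
#' (pure or, by default, also in mixture).
#'
#' @param aaf a [PoolAAF] with design in `colData`, or a matrix plus
#'   `design`.
#' @param focal `"Merks"` or `"Meloni"`.
#' @param design design table (defaults to `colData(aaf)`).
#' @param min_aaf polymorphism threshold for the focal condition (default
#'   0, i.e. strictly positive); raise to guard against residual error
#'   calls.
#' @param mixture_counts include mixed-cultivar plots (compositions 5-7)
#'   in the focal "polymorphic" condition (default TRUE).
#' @return character vector of locus keys.
#' @export
privateSNPs <- function(aaf, focal = c("Merks", "Meloni"), design = NULL,
                        min_aaf = 0, mixture_counts = TRUE) {
    focal <- match.arg(focal)
    m <- if (is(aaf, "PoolAAF")) aafValues(aaf) else as.matrix(aaf)
    if (is.null(design) && is(aaf, "PoolAAF"))
        design <- as.data.frame(colData(aaf))
    other <- setdiff(c("Merks", "Meloni"), focal)
    pure_other <- design$ryegrass_content == other
    if (!any(pure_other))
        stop("design has no pure ", other, " plots")
    has_focal <- if (mixture_counts)
        design$ryegrass_content %in% c(focal, "both")
    else design$ryegrass_content == focal
    zero_in_other <- rowSums(m[, pure_other, drop = FALSE] > 0,
                             na.rm = TRUE) == 0L &
        rowSums(!is.na(m[, pure_other, drop = FALSE])) > 0L
    poly_in_focal <- rowSums(m[, has_focal, drop = FALSE] > min_aaf,
                             na.rm = TRUE) > 0L
    rownames(m)[zero_in_other & poly_in_focal]
}

#' Cultivar abundance from private SNPs
#'
#' The mean AAF over a cultivar's private SNPs scales with that cultivar's
#' proportion in the pooled sample. Each sample's mean private AAF is
#' normalized by the average over pure plots of the focal cultivar, giving
#' a proportion estimate `w_hat` per sample and focal cultivar.
#'
#' @param aaf a [PoolAAF] with design in `colData`, or a matrix plus
#'   `design`.
#' @param private_merks,private_meloni locus-key sets from [privateSNPs()].
#' @param design design table (defaults to `colData(aaf)`).
#' @return data.frame, one row per sample: `sample_id`, `composition`,
#'   `replicate`, `year`, `mean_private_merks`, `mean_private_meloni`,
#'   `w_merks`, `w_meloni`.
#' @export
cultivarAbundance <- function(aaf, private_merks, private_meloni,
                              design = NULL) {
    m <- if (is(aaf, "PoolAAF")) aafValues(aaf) else as.matrix(aaf)
    if (is.null(design) && is(aaf, "PoolAAF"))
        design <- as.data.frame(colData(aaf))
    if (length(private_merks) == 0L || length(private_meloni) == 0L)
        stop("both private SNP sets must be non-empty")
    mm <- colMeans(m[as.character(private_merks), , drop = FALSE],
                   na.rm = TRUE)
    ml <- colMeans(m[as.character(private_meloni), , drop = FALSE],
                   na.rm = TRUE)
    what <- function(means, cultivar) {
        pure <- design$ryegrass_content == cultivar
        ref <- mean(means[pure])
        if (!is.finite(ref) || ref == 0) {
            warning("mean private AAF over pure ", cultivar,
                    " plots is 0; proportion estimate undefined")
            return(rep(NA_real_, length(means)))
        }
        means / ref
    }
    data.frame(sample_id = design$sample_id,
               composition = design$composition,
               replicate = design$replicate, year = design$year,
               mean_private_merks = as.numeric(mm),
               mean_private_meloni = as.numeric(ml),
               w_merks = as.numeric(what(mm, "Merks")),
               w_meloni = as.numeric(what(ml, "Meloni")),
               row.names = NULL, stringsAsFactors = FALSE)
}
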