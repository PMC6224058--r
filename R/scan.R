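## Per-SNP selection scan.
##
## Model: AAF ~ PC1 + S + S:R + S:Y, fitted per SNP by sequential
## (Type-I) least squares in that term order. PC1 absorbs the cultivar
## differentiation and cultivar-proportion drift; S the remaining
## composition differences; S:R replicate-plot differences; S:Y the
## composition-consistent temporal change that selection would produce.
## The scan statistic is the mean-square ratio MSS(S:Y) / MSS(residual)
## (the literal MSS(S:Y) / RSS quotient is emitted alongside). Because no
## parametric null is trusted, the null is fitted to the observed
## statistics by maximum likelihood over several families and p-values are
## upper-tail probabilities of the best (lowest-AIC) fit.

.scanDesign <- function(design, pc1_scores) {
    stopifnot(length(pc1_scores) == nrow(design))
    dat <- data.frame(pc1 = as.numeric(pc1_scores),
                      S = factor(design$composition),
                      R = factor(design$replicate),
                      Y = factor(design$year))
    X <- model.matrix(~ pc1 + S + S:R + S:Y, data = dat)
    qrx <- qr(X)
    if (qrx$rank < ncol(X))
        stop("rank-deficient scan design (", qrx$rank, " < ", ncol(X), ")")
    if (!identical(qrx$pivot, seq_len(ncol(X))))
        stop("unexpected column pivoting in scan design QR")
    asg <- attr(X, "assign")        # 0 = intercept, 1 = pc1, 2 = S, ...
    labels <- c("PC1", "S", "S:R", "S:Y")
    df <- vapply(1:4, function(k) sum(asg == k), integer(1))
    names(df) <- labels
    list(Q = qr.Q(qrx), assign = asg, labels = labels, df = df,
         n = nrow(X), p = ncol(X))
}

#' Sequential variance decomposition for one SNP
#'
#' Partitions the total sum of squares of one SNP's AAF values over the
#' design into sequential (Type-I) components in the fixed term order
#' PC1, S, S:R, S:Y, residual. The components sum exactly to the total.
#' On the full 56-sample design the term degrees of freedom are 1, 6, 7,
#' 21 with 20 residual.
#'
#' @param aaf_row numeric vector: one SNP's AAF across all design samples
#'   (complete, no missing values).
#' @param design design table ([trialDesign()]).
#' @param pc1_scores per-sample scores of PC1 from [pcaAAF()].
#' @return list of class `VarianceDecomposition`: `tss`, `ss` (named
#'   vector over PC1, S, S:R, S:Y), `rss`, `df` (with `residual`), `mss`,
#'   `degenerate` flag (TRUE when TSS or RSS is 0).
#' @export
decomposeVariance <- function(aaf_row, design, pc1_scores) {
    if (anyNA(aaf_row))
        stop("AAF row has missing values; the scan needs complete rows")
    sd <- .scanDesign(design, pc1_scores)
    dec <- .decomposeMatrix(matrix(aaf_row, ncol = 1L), sd)
    out <- list(tss = dec$tss[1L],
                ss = setNames(dec$ss[1L, ], sd$labels),
                rss = dec$rss[1L],
                df = c(sd$df, residual = sd$n - sd$p),
                mss = setNames(dec$ss[1L, ] / sd$df, sd$labels),
                mss_residual = dec$rss[1L] / (sd$n - sd$p),
                degenerate = dec$degenerate[1L])
    class(out) <- "VarianceDecomposition"
    out
}

## Y: samples x loci matrix; returns per-locus sequential SS by term block.
## A component is "zero" relative to the uncorrected total (degenerate
## flag), not against an absolute epsilon.
.decomposeMatrix <- function(Y, sd) {
    eff <- crossprod(sd$Q, Y)                     # p x loci
    ss <- t(rowsum(eff^2, group = sd$assign))     # loci x terms (incl 0)
    total <- colSums(Y^2)
    fitted_ss <- rowSums(ss)
    rss <- pmax(0, total - fitted_ss)
    tss <- pmax(0, total - ss[, 1L])              # corrected total
    tol <- 1e-12 * pmax(total, .Machine$double.eps)
    list(ss = ss[, -1L, drop = FALSE], rss = rss, tss = tss,
         degenerate = tss <= tol | rss <= tol)
}

#' Scan statistic of a variance decomposition
#'
#' `MSS(S:Y) / MSS(residual)` (an F-like mean-square ratio; the default)
#' and the literal quotient `MSS(S:Y) / RSS`. `NA` when the residual is 0.
#'
#' @param vd a [decomposeVariance()] result.
#' @return named numeric vector `c(statistic, statistic_literal)`.
#' @export
scanStatistic <- function(vd) {
    if (vd$degenerate)
        return(c(statistic = NA_real_, statistic_literal = NA_real_))
    c(statistic = vd$mss[["S:Y"]] / vd$mss_residual,
      statistic_literal = vd$mss[["S:Y"]] / vd$rss)
}

#' Variance decomposition of every SNP in an AAF matrix
#'
#' Vectorized [decomposeVariance()] over all loci (one QR of the shared
#' design, one matrix product for all SNPs).
#'
#' @param aaf a [PoolAAF] (complete) or loci x samples matrix.
#' @param design design table; defaults to `colData(aaf)`.
#' @param pc1_scores PC1 scores; computed via [pcaAAF()] when omitted.
#' @return data.frame, one row per SNP: `locus`, `tss`, `ss_pc1`, `ss_s`,
#'   `ss_sr`, `ss_sy`, `rss`, `mss_sy`, `mss_residual`, `statistic`,
#'   `statistic_literal`, `degenerate`.
#' @export
scanAAF <- function(aaf, design = NULL, pc1_scores = NULL) {
    m <- if (is(aaf, "PoolAAF")) aafValues(aaf) else as.matrix(aaf)
    if (is.null(design) && is(aaf, "PoolAAF"))
        design <- as.data.frame(colData(aaf))
    if (anyNA(m))
        stop("AAF matrix has missing values; run filterCascade first")
    if (is.null(pc1_scores))
        pc1_scores <- pcaAAF(m, design = design)$scores[, 1L]
    sd <- .scanDesign(design, pc1_scores)
    dec <- .decomposeMatrix(t(m), sd)
    df_res <- sd$n - sd$p
    mss_sy <- dec$ss[, 4L] / sd$df[["S:Y"]]
    mss_res <- dec$rss / df_res
    degen <- dec$degenerate
    stat <- ifelse(degen, NA_real_, mss_sy / mss_res)
    lit <- ifelse(degen, NA_real_, mss_sy / dec$rss)
    data.frame(locus = rownames(m), tss = dec$tss,
               ss_pc1 = dec$ss[, 1L], ss_s = dec$ss[, 2L],
               ss_sr = dec$ss[, 3L], ss_sy = dec$ss[, 4L],
               rss = dec$rss, mss_sy = mss_sy, mss_residual = mss_res,
               statistic = stat, statistic_literal = lit,
               degenerate = degen, row.names = NULL,
               stringsAsFactors = FALSE)
}

#' Fit candidate null distributions to the scan statistics
#'
#' Maximum-likelihood fits of the log-normal, gamma, chi-square and F
#' families to the finite positive statistics; the family with the lowest
#' AIC is selected. The log-normal fit is parameterized by the mean and
#' standard deviation of the log statistics.
#'
#' @param statistics numeric vector of scan statistics.
#' @param families subset of `c("lognormal", "gamma", "chisquare", "f")`.
#' @return list of class `NullFitList`; each element has `family`,
#'   `params`, `loglik`, `aic`, `selected`. Attribute `n_excluded` counts
#'   dropped non-finite/non-positive values.
#' @export
fitNull <- function(statistics,
                    families = c("lognormal", "gamma", "chisquare", "f")) {
    families <- match.arg(families, several.ok = TRUE)
    x <- statistics[is.finite(statistics)]
    excluded <- length(statistics) - sum(is.finite(statistics) &
                                         statistics > 0)
    x <- x[x > 0]
    if (length(x) < 100L)
        stop("need at least 100 finite positive statistics, got ",
             length(x))
    if (sd(log(x)) == 0)
        stop("degenerate fit: statistics are constant")
    if (excluded > 0)
        message(excluded, " non-positive/non-finite statistic(s) excluded")
    fit1 <- function(fam) {
        fd <- tryCatch(suppressWarnings(switch(fam,
            lognormal = MASS::fitdistr(x, "lognormal"),
            gamma = MASS::fitdistr(x, "gamma"),
            chisquare = MASS::fitdistr(x, "chi-squared",
                start = list(df = mean(x)), method = "Brent",
                lower = 1e-3, upper = 1e4),
            f = MASS::fitdistr(x, "f",
                start = list(df1 = 10, df2 = 10)))),
            error = function(e) NULL)
        if (is.null(fd)) return(NULL)
        ll <- as.numeric(stats::logLik(fd))
        list(family = fam, params = fd$estimate, loglik = ll,
             aic = 2 * length(fd$estimate) - 2 * ll, selected = FALSE)
    }
    fits <- Filter(Negate(is.null), lapply(families, fit1))
    if (length(fits) == 0L)
        stop("no null family could be fitted")
    best <- which.min(vapply(fits, `[[`, numeric(1), "aic"))
    fits[[best]]$selected <- TRUE
    names(fits) <- vapply(fits, `[[`, character(1), "family")
    structure(fits, n_excluded = excluded, class = "NullFitList")
}

#' @export
print.NullFitList <- function(x, ...) {
    for (f in x)
        cat(sprintf("%-10s AIC %.1f%s  (%s)\n", f$family, f$aic,
                    if (f$selected) " *" else "  ",
                    paste(names(f$params),
                          signif(f$params, 4), sep = "=",
                          collapse = ", ")))
    invisible(x)
}

selectedFit <- function(fits) fits[[which(vapply(fits, `[[`, logical(1),
                                                 "selected"))]]

.nullUpperTail <- function(q, fit) {
    p <- fit$params
    switch(fit$family,
        lognormal = plnorm(q, p[["meanlog"]], p[["sdlog"]],
                           lower.tail = FALSE),
        gamma = pgamma(q, shape = p[["shape"]], rate = p[["rate"]],
                       lower.tail = FALSE),
        chisquare = pchisq(q, df = p[["df"]], lower.tail = FALSE),
        f = pf(q, p[["df1"]], p[["df2"]], lower.tail = FALSE))
}

#' P-values, FDR calls and uniformity diagnostic
#'
#' Upper-tail p-values of the scan statistics under the selected null fit,
#' Benjamini-Hochberg q-values, outlier calls at the given FDR, and a
#' Kolmogorov-Smirnov test of the p-values against uniformity (a well
#' calibrated empirical null gives uniform p-values and no outliers on
#' neutral data).
#'
#' @param statistics numeric scan statistics (`NA` allowed).
#' @param fit a [fitNull()] result (the selected family is used) or a
#'   single fit element.
#' @param fdr false-discovery-rate threshold (default 0.05).
#' @return list: `table` (data.frame `statistic`, `p`, `q`, `outlier`),
#'   `n_outliers`, `ks_statistic`, `ks_p`, `family`.
#' @export
pvaluesAndCalls <- function(statistics, fit, fdr = 0.05) {
    if (inherits(fit, "NullFitList")) fit <- selectedFit(fit)
    p <- rep(NA_real_, length(statistics))
    ok <- is.finite(statistics) & statistics > 0
    p[ok] <- .nullUpperTail(statistics[ok], fit)
    q <- rep(NA_real_, length(statistics))
    q[ok] <- p.adjust(p[ok], method = "BH")
    outlier <- !is.na(q) & q < fdr
    ks <- suppressWarnings(ks.test(p[ok], "punif"))
    list(table = data.frame(statistic = statistics, p = p, q = q,
                            outlier = outlier),
         n_outliers = sum(outlier), ks_statistic = unname(ks$statistic),
         ks_p = ks$p.value, family = fit$family)
}

#' Full selection scan
#'
#' Convenience wrapper: PCA for the PC1 covariate, per-SNP variance
#' decomposition, empirical null fit and p-values.
#'
#' @inheritParams scanAAF
#' @inheritParams fitNull
#' @inheritParams pvaluesAndCalls
#' @return list: `snps` (the [scanAAF()] table joined with `p`, `q`,
#'   `outlier`), `fits`, `calls` (the [pvaluesAndCalls()] summary), `pc1`.
#' @export
selectionScan <- function(aaf, design = NULL, pc1_scores = NULL,
                          families = c("lognormal", "gamma", "chisquare",
                                       "f"),
                          fdr = 0.05) {
    if (is.null(design) && is(aaf, "PoolAAF"))
        design <- as.data.frame(colData(aaf))
    if (is.null(pc1_scores))
        pc1_scores <- pcaAAF(aaf, design = design)$scores[, 1L]
    snps <- scanAAF(aaf, design, pc1_scores)
    fits <- fitNull(snps$statistic, families = families)
    calls <- pvaluesAndCalls(snps$statistic, fits, fdr = fdr)
    snps$p <- calls$table$p
    snps$q <- calls$table$q
    snps$outlier <- calls$table$outlier
    list(snps = snps, fits = fits, calls = calls, pc1 = pc1_scores)
}
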