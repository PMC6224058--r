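#' @import methods
#' @importFrom stats aov anova as.formula coef dbinom lm logLik median
#'   model.matrix na.omit p.adjust pchisq plnorm pgamma pf prcomp quantile
#'   rbinom rnbinom rnorm runif sd setNames cor ks.test plogis qlogis var
#' @importFrom utils read.delim write.table head
NULL

#' Accessors for pool-GBS containers
#'
#' `refCounts()`, `altCounts()` and `extraCounts()` return the per-locus,
#' per-sample read-count matrices of a [PoolCounts] object (reference allele,
#' alternative allele, and any further alleles observed at the site).
#' `aafValues()` returns the alternative-allele-frequency matrix of a
#' [PoolAAF] object, with `NA` marking missing estimates. `genoCalls()`
#' returns the genotype-dose matrix (0/1/2, `NA` missing) of a
#' [GenotypeCalls] object.
#'
#' @param x a `PoolCounts`, `PoolAAF` or `GenotypeCalls` object.
#' @return an integer or numeric matrix with loci as rows and samples as
#'   columns.
#' @examples
#' pc <- toyCounts()
#' refCounts(pc)[1:2, ]
#' @name pool-accessors
NULL

#' @rdname pool-accessors
#' @export
setGeneric("refCounts", function(x) standardGeneric("refCounts"))

#' @rdname pool-accessors
#' @export
setGeneric("altCounts", function(x) standardGeneric("altCounts"))

#' @rdname pool-accessors
#' @export
setGeneric("extraCounts", function(x) standardGeneric("extraCounts"))

#' @rdname pool-accessors
#' @export
setGeneric("aafValues", function(x) standardGeneric("aafValues"))

#' @rdname pool-accessors
#' @export
setGeneric("genoCalls", function(x) standardGeneric("genoCalls"))
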