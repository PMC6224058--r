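#' SNP filter settings
#'
#' Bundles the locus-filter thresholds with the dataset-mode presets used
#' for the trial: `"pool"` (the 56 field pools: per-cell depth >= 30, no
#' missing data allowed, total-depth ceiling 150k, mean-AAF band 10-90%)
#' and `"individual"` (40 individually genotyped plants: total-depth
#' ceiling 6k, up to 5 missing calls per locus, no AAF band). The
#' validation experiment's replicate-pool ceilings (3.5k single pools, 7k
#' merged pools) can be set through `max_total_depth`.
#'
#' @param mode `"pool"` or `"individual"` preset.
#' @param min_depth minimum per-cell total read depth; shallower cells
#'   become missing.
#' @param max_total_depth ceiling on the per-locus depth summed over
#'   samples (removes collapsed repeats).
#' @param max_missing maximum number of missing cells tolerated per locus.
#' @param aaf_band numeric length-2: retained band of the per-locus AAF
#'   summary, or `NULL` to skip. Bounds are inclusive by default.
#' @param band_inclusive retain loci exactly on the band bounds (default
#'   TRUE).
#' @param band_scope `"mean"` applies the band to the mean AAF across
#'   samples; `"any-sample"` retains a locus if any single sample falls
#'   inside the band.
#' @param remove_multiallelic drop loci where reads supporting a third
#'   allele were observed in any sample.
#' @return list of class `FilterConfig`.
#' @export
filterConfig <- function(mode = c("pool", "individual"),
                         min_depth = 30L,
                         max_total_depth = if (mode == "pool") 150000L
                                           else 6000L,
                         max_missing = if (mode == "pool") 0L else 5L,
                         aaf_band = if (mode == "pool") c(0.10, 0.90)
                                    else NULL,
                         band_inclusive = TRUE,
                         band_scope = c("mean", "any-sample"),
                         remove_multiallelic = TRUE) {
    mode <- match.arg(mode)
    band_scope <- match.arg(band_scope)
    if (!is.null(aaf_band))
        stopifnot(length(aaf_band) == 2L, aaf_band[1] >= 0,
                  aaf_band[1] < aaf_band[2], aaf_band[2] <= 1)
    stopifnot(min_depth >= 0, max_total_depth > 0, max_missing >= 0)
    structure(list(mode = mode, min_depth = as.integer(min_depth),
                   max_total_depth = max_total_depth,
                   max_missing = as.integer(max_missing),
                   aaf_band = aaf_band, band_inclusive = band_inclusive,
                   band_scope = band_scope,
                   remove_multiallelic = remove_multiallelic),
              class = "FilterConfig")
}

#' The locus filter cascade
#'
#' Applies the filters in a fixed, auditable order: (1) cells with total
#' depth below `min_depth` become missing; (2) loci whose depth summed over
#' samples exceeds `max_total_depth` are dropped; (3) loci with more than
#' `max_missing` missing cells are dropped; (4) loci with a third allele
#' observed in any sample are dropped; (5) loci whose AAF summary falls
#' outside the retained band are dropped. The report records the surviving
#' locus count after each step, so the effect of the (order-sensitive)
#' cascade is auditable. Running the cascade on its own output changes
#' nothing.
#'
#' @param counts a [PoolCounts] object.
#' @param aaf the matching [PoolAAF] (same loci and samples).
#' @param config a [filterConfig()].
#' @return list with `aaf` and `counts` restricted to surviving loci (AAF
#'   cells masked by the depth step are `NA`) and `report`, a data.frame of
#'   per-step locus counts plus the number of masked cells.
#' @export
filterCascade <- function(counts, aaf, config = filterConfig("pool")) {
    stopifnot(identical(rownames(counts), rownames(aaf)),
              identical(colnames(counts), colnames(aaf)))
    depth <- refCounts(counts) + altCounts(counts) + extraCounts(counts)
    m <- aafValues(aaf)
    steps <- data.frame(step = "input", loci = nrow(m),
                        stringsAsFactors = FALSE)
    ## 1. per-cell depth
    shallow <- is.na(depth) | depth < config$min_depth
    masked <- sum(shallow & !is.na(m))
    m[shallow] <- NA_real_
    ## 2. excessive total depth
    keep <- rowSums(depth, na.rm = TRUE) <= config$max_total_depth
    steps <- rbind(steps, data.frame(step = "total_depth",
                                     loci = sum(keep)))
    ## 3. missing data
    keep <- keep & rowSums(is.na(m)) <= config$max_missing
    steps <- rbind(steps, data.frame(step = "missing", loci = sum(keep)))
    ## 4. multi-allelic
    if (config$remove_multiallelic) {
        keep <- keep & rowSums(extraCounts(counts) > 0, na.rm = TRUE) == 0L
        steps <- rbind(steps, data.frame(step = "multiallelic",
                                         loci = sum(keep)))
    }
    ## 5. AAF band
    if (!is.null(config$aaf_band)) {
        lo <- config$aaf_band[1]; hi <- config$aaf_band[2]
        inside <- function(x) if (config$band_inclusive)
            !is.na(x) & x >= lo & x <= hi
        else !is.na(x) & x > lo & x < hi
        in_band <- if (config$band_scope == "mean")
            inside(rowMeans(m, na.rm = TRUE))
        else rowSums(inside(m)) > 0L
        keep <- keep & in_band
        steps <- rbind(steps, data.frame(step = "aaf_band",
                                         loci = sum(keep)))
    }
    if (!any(keep))
        warning("no loci survive the filter cascade")
    out_aaf <- PoolAAF(rowRanges(aaf)[keep], m[keep, , drop = FALSE],
                       design = colData(aaf))
    out_counts <- counts[keep, ]
    steps$masked_cells <- c(masked, rep(NA, nrow(steps) - 1L))
    list(aaf = out_aaf, counts = out_counts, report = steps)
}

#' Read-depth saturation curves
#'
#' How many reference positions reach a given minimum depth as more reads
#' are mapped. Reads (given by their mapped positions) are subsampled
#' without replacement along a single seeded permutation, so curves at
#' increasing subsample sizes are nested and therefore non-decreasing.
#'
#' @param read_positions vector of mapped positions, one entry per read
#'   (a multiset; any atomic type identifying a position).
#' @param grid subsample sizes (numbers of reads).
#' @param thresholds minimum-depth thresholds (default 10, 30, 100, 300).
#' @param seed permutation seed.
#' @return data.frame with columns `reads`, `threshold`, `positions`.
#' @export
saturationCurve <- function(read_positions, grid,
                            thresholds = c(10L, 30L, 100L, 300L),
                            seed = 1L) {
    stopifnot(all(grid <= length(read_positions)), all(grid >= 0))
    set.seed(seed)
    perm <- sample.int(length(read_positions))
    grid <- sort(unique(as.integer(grid)))
    out <- expand.grid(reads = grid, threshold = sort(thresholds),
                       KEEP.OUT.ATTRS = FALSE)
    out$positions <- NA_integer_
    for (g in grid) {
        depth <- table(read_positions[perm[seq_len(g)]])
        for (t in thresholds)
            out$positions[out$reads == g & out$threshold == t] <-
                sum(depth >= t)
    }
    out
}
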