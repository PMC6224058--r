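## Trial design: 7 seed compositions x 2 replicate plots x 4 years.
##
## Composition -> cultivar content (the sown seed mixtures):
##   1 Merks 100%                      5 Merks+Meloni / Lemmon+Crossway
##   2 Meloni 100%                     6 Merks+Meloni / Lemmon
##   3 Merks 70% / Lemmon+Crossway     7 Merks+Meloni / Crossway
##   4 Meloni 70% / Lemmon+Crossway

.COMP_RYEGRASS <- c("Merks", "Meloni", "Merks", "Meloni", "both", "both",
                    "both")
.COMP_CLOVER <- c("none", "none", "both", "both", "both", "Lemmon",
                  "Crossway")

#' Content of the sown seed compositions
#'
#' Maps seed-composition numbers (1-7) to the ryegrass and red-clover
#' cultivar content of the sown mixture. Compositions 1-2 are ryegrass
#' monocultures (Merks, Meloni), 3-4 combine one ryegrass cultivar with both
#' clover cultivars, and 5-7 combine both ryegrass cultivars with both, one
#' (Lemmon), or the other (Crossway) clover cultivar.
#'
#' @param composition integer vector in 1..7.
#' @return data.frame with columns `composition`, `ryegrass_content`
#'   (`"Merks"`, `"Meloni"` or `"both"`) and `clover_content` (`"none"`,
#'   `"Lemmon"`, `"Crossway"` or `"both"`).
#' @export
#' @examples
#' compositionContents(1:7)
compositionContents <- function(composition) {
    composition <- as.integer(composition)
    if (any(is.na(composition)) || any(composition < 1L | composition > 7L))
        stop("seed composition must be an integer in 1..7")
    data.frame(composition = composition,
               ryegrass_content = .COMP_RYEGRASS[composition],
               clover_content = .COMP_CLOVER[composition],
               stringsAsFactors = FALSE)
}

#' The full field-trial sampling design
#'
#' Builds the design table of the four-year sward trial: 7 seed compositions
#' sown in 2 replicate plots (A/B) give 14 field plots; each plot is sampled
#' once per year for 4 years, giving 56 population samples of 40 ryegrass
#' plants each. Cultivar contents are derived from the composition (see
#' [compositionContents()]).
#'
#' @param years integer vector of sampling years (default 1:4).
#' @param compositions integer vector of seed compositions (default 1:7).
#' @return data.frame with one row per population sample and columns
#'   `sample_id`, `plot_id` (1-14), `composition`, `replicate` ("A"/"B"),
#'   `year`, `ryegrass_content`, `clover_content`.
#' @seealso [tissuePools()] for the replicate-pool expansion,
#'   [readDesignTable()] for reading a design from file.
#' @export
#' @examples
#' d <- trialDesign()
#' nrow(d)  # 56
trialDesign <- function(years = 1:4, compositions = 1:7) {
    grid <- expand.grid(year = as.integer(years), replicate = c("A", "B"),
                        composition = as.integer(compositions),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    grid <- grid[order(grid$composition, grid$replicate, grid$year), ,
                 drop = FALSE]
    plots <- expand.grid(replicate = c("A", "B"), composition = 1:7,
                         stringsAsFactors = FALSE)
    plots$plot_id <- seq_len(nrow(plots))
    d <- merge(grid, plots, by = c("composition", "replicate"), sort = FALSE)
    d$sample_id <- sprintf("S%d%s_Y%d", d$composition, d$replicate, d$year)
    d <- cbind(d[c("sample_id", "plot_id", "composition", "replicate",
                   "year")],
               compositionContents(d$composition)[-1])
    rownames(d) <- d$sample_id
    validateDesign(d)
    d
}

#' Expand population samples to replicate tissue pools
#'
#' Each set of 40 sampled leaves is pooled in replicate (equal 5 mg tissue
#' per leaf) before library preparation; the full trial therefore yields
#' twice as many pooled samples as population samples (112 for 56).
#'
#' @param design a design table from [trialDesign()] or [readDesignTable()].
#' @param n_pools tissue-pool replicates per population sample (default 2).
#' @return data.frame with one row per tissue pool: the design columns plus
#'   `pool_replicate` and `pool_id`.
#' @export
#' @examples
#' nrow(tissuePools(trialDesign()))  # 112
tissuePools <- function(design, n_pools = 2L) {
    stopifnot(n_pools >= 1L)
    idx <- rep(seq_len(nrow(design)), each = n_pools)
    out <- design[idx, , drop = FALSE]
    out$pool_replicate <- rep(seq_len(n_pools), nrow(design))
    out$pool_id <- sprintf("%s_P%d", out$sample_id, out$pool_replicate)
    rownames(out) <- out$pool_id
    out
}

validateDesign <- function(d) {
    triple <- paste(d$composition, d$replicate, d$year)
    if (anyDuplicated(triple))
        stop("duplicate (composition, replicate, year) triple: ",
             paste(unique(triple[duplicated(triple)]), collapse = "; "))
    if (any(d$composition < 1L | d$composition > 7L))
        stop("seed composition outside 1..7")
    if (!all(d$replicate %in% c("A", "B")))
        stop("replicate must be 'A' or 'B'")
    invisible(d)
}

#' Read / write a sample design table
#'
#' The design TSV has columns `sample_id`, `seed_composition` (or
#' `composition`), `replicate`, `year`; cultivar contents are derived from
#' the composition, so files need not carry them. A design covering fewer
#' than the 56 samples of the full trial is accepted with a warning.
#'
#' @param path file path of a tab-separated design table.
#' @return data.frame in the [trialDesign()] layout.
#' @export
readDesignTable <- function(path) {
    tab <- read.delim(path, stringsAsFactors = FALSE)
    names(tab)[names(tab) == "seed_composition"] <- "composition"
    need <- c("sample_id", "composition", "replicate", "year")
    if (!all(need %in% names(tab)))
        stop("design table needs columns ", paste(need, collapse = ", "))
    comp <- suppressWarnings(as.integer(tab$composition))
    if (any(is.na(comp)) || any(comp < 1L | comp > 7L))
        stop("seed composition outside 1..7 in design table")
    d <- data.frame(sample_id = as.character(tab$sample_id),
                    plot_id = if ("plot_id" %in% names(tab))
                        as.integer(tab$plot_id)
                    else match(paste(comp, tab$replicate),
                               paste(rep(1:7, each = 2), c("A", "B"))),
                    composition = comp,
                    replicate = as.character(tab$replicate),
                    year = as.integer(tab$year),
                    stringsAsFactors = FALSE)
    d <- cbind(d, compositionContents(d$composition)[-1])
    rownames(d) <- d$sample_id
    validateDesign(d)
    if (nrow(d) < 56L)
        warning("partial design: ", nrow(d), " of 56 samples")
    d
}

#' @param design a design table.
#' @rdname readDesignTable
#' @export
writeDesignTable <- function(design, path) {
    out <- design[c("sample_id", "plot_id", "composition", "replicate",
                    "year")]
    names(out)[names(out) == "composition"] <- "seed_composition"
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

## plots in which only the given ryegrass cultivar was sown
pureCompositions <- function(cultivar) {
    which(.COMP_RYEGRASS == cultivar)
}

## plots containing the cultivar at all (pure or in mixture)
containingCompositions <- function(cultivar) {
    which(.COMP_RYEGRASS %in% c(cultivar, "both"))
}
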