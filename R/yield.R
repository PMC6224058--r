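## Herbage dry-matter arithmetic, botanical fractions, and the three yield
## hypothesis tests via linear mixed models (ML fits, likelihood-ratio
## tests on the fixed effects; replicate and year are independent random
## intercepts).

#' Herbage dry-matter weight
#'
#' `DMW = fresh_total * (sub_dry / sub_fresh) / area`, reported in tonnes
#' per hectare: the plot's fresh harvest weight scaled by the dry-matter
#' fraction of a dried subsample.
#'
#' @param fresh_total fresh harvest weight of the plot (kg).
#' @param sub_fresh,sub_dry fresh and dried weight of the subsample (any
#'   common unit, e.g. g).
#' @param area harvested area (ha).
#' @return DMW in t/ha.
#' @export
#' @examples
#' dryMatterWeight(10.8, 450, 90, area = 10.8 / 1e4)  # 2 t/ha
dryMatterWeight <- function(fresh_total, sub_fresh, sub_dry, area) {
    stopifnot(all(fresh_total >= 0), all(area > 0))
    if (any(sub_fresh <= 0))
        stop("subsample fresh weight must be positive")
    if (any(sub_dry > sub_fresh))
        stop("subsample dry weight exceeds its fresh weight")
    fresh_total * (sub_dry / sub_fresh) / area / 1000
}

#' Botanical fractions from sorted subsamples
#'
#' Each subsample is separated into grass, clover and weed, the fractions
#' computed from the dry weights, and the plot value is the unweighted mean
#' over subsamples (four per plot in the trial). Subsamples with zero total
#' dry weight are excluded with a warning.
#'
#' @param subsamples numeric matrix, one row per subsample, columns grass,
#'   clover, weed dry weights (a vector is taken as one subsample).
#' @return named numeric vector of mean fractions summing to 1.
#' @export
#' @examples
#' botanicalFractions(rbind(c(60, 40, 0), c(60, 40, 0)))
botanicalFractions <- function(subsamples) {
    m <- if (is.null(dim(subsamples))) matrix(subsamples, nrow = 1L)
         else as.matrix(subsamples)
    if (ncol(m) != 3L)
        stop("expected columns: grass, clover, weed dry weights")
    tot <- rowSums(m)
    if (any(tot == 0)) {
        warning(sum(tot == 0), " zero-total subsample(s) excluded")
        m <- m[tot > 0, , drop = FALSE]
        tot <- tot[tot > 0]
    }
    if (nrow(m) == 0L)
        stop("no usable subsample")
    setNames(colMeans(m / tot), c("grass", "clover", "weed"))
}

## per-hypothesis composition subsets and fixed-effect factors
.hypothesisData <- function(yields, model) {
    comps <- switch(as.character(model), "1" = 1:4, "2" = 3:5, "3" = 5:7,
                    stop("model must be 1, 2 or 3"))
    d <- yields[yields$composition %in% comps, , drop = FALSE]
    if (nrow(d) == 0L)
        stop("no yield rows for compositions ",
             paste(range(comps), collapse = "-"))
    cc <- compositionContents(d$composition)
    d$L <- factor(cc$ryegrass_content)
    d$T <- factor(if (model == 1) ifelse(cc$clover_content == "none",
                                         "none", "clover")
                  else cc$clover_content)
    d$R <- factor(d$replicate)
    d$Y <- factor(d$year)
    d
}

.responseColumn <- function(response) {
    switch(response, total = "dmw_total", grass = "dmw_grass",
           clover = "dmw_clover",
           stop("response must be total, grass or clover"))
}

.fitLmm <- function(formula, data) {
    ctl <- lme4::lmerControl(check.conv.singular = "ignore")
    suppressMessages(lme4::lmer(formula, data = data, REML = FALSE,
                                control = ctl))
}

#' Fit one of the three yield mixed models
#'
#' Model 1 (`resp ~ L * T`) on compositions 1-4 tests the ryegrass cultivar
#' (L: Merks/Meloni), the presence of clover (T) and their interaction;
#' model 2 (`resp ~ L`) on compositions 3-5 tests the ryegrass component
#' (Merks/Meloni/both); model 3 (`resp ~ T`) on compositions 5-7 tests the
#' clover component (Lemmon/Crossway/both). All models add independent
#' random intercepts for replicate and year and are fitted by maximum
#' likelihood (required for likelihood-ratio tests on fixed effects).
#'
#' @param yields a yield table ([simulateYield()] or [readYieldTable()]):
#'   annual rows per plot-year with `composition`, `replicate`, `year` and
#'   the DMW response columns.
#' @param model 1, 2 or 3.
#' @param response `"total"`, `"grass"` or `"clover"`.
#' @param fixed model formula right-hand side for the fixed part; defaults
#'   to the model's full fixed structure (used internally to build reduced
#'   models).
#' @return a fitted `lmerMod` (ML).
#' @export
fitYieldModel <- function(yields, model = 1, response = "total",
                          fixed = NULL) {
    d <- .hypothesisData(yields, model)
    d$resp <- d[[.responseColumn(response)]]
    if (is.null(fixed))
        fixed <- switch(as.character(model), "1" = "L * T", "2" = "L",
                        "3" = "T")
    f <- as.formula(paste("resp ~", fixed, "+ (1 | R) + (1 | Y)"))
    .fitLmm(f, d)
}

#' Likelihood-ratio test of nested mixed models
#'
#' `2 * (logLik(full) - logLik(reduced))` against a chi-square with the
#' parameter-count difference as degrees of freedom. Both fits must be ML
#' fits on the same rows; a reduced model with at least as many parameters
#' as the full one is rejected as non-nested.
#'
#' @param full,reduced fitted models from [fitYieldModel()].
#' @return list: `chisq`, `df`, `p`.
#' @export
likelihoodRatioTest <- function(full, reduced) {
    llf <- logLik(full); llr <- logLik(reduced)
    df <- attr(llf, "df") - attr(llr, "df")
    if (df < 0)
        stop("models are not nested: reduced has more parameters")
    if (stats::nobs(full) != stats::nobs(reduced))
        stop("models were fitted on different rows")
    stat <- max(0, 2 * (as.numeric(llf) - as.numeric(llr)))
    list(chisq = stat, df = df,
         p = if (df == 0) 1 else pchisq(stat, df, lower.tail = FALSE))
}

#' The three yield hypothesis tests
#'
#' Runs the full battery of likelihood-ratio tests on a yield table and
#' returns them in the layout of the trial's yield-effects table: H1
#' (compositions 1-4, model 1) tests the L x T interaction, the ryegrass
#' cultivar L and the clover presence T on the total DMW; H2 (compositions
#' 3-5, model 2) tests the ryegrass component on the total, grass and
#' clover DMW; H3 (compositions 5-7, model 3) does the same for the clover
#' component. Main effects in H1 are tested by dropping them from the
#' additive model.
#'
#' @param yields a yield table (see [fitYieldModel()]).
#' @return data.frame with columns `hypothesis`, `test`, `model`,
#'   `response`, `compositions`, `component`, `chisq`, `df`, `p`.
#' @export
yieldHypothesisTests <- function(yields) {
    rows <- list()
    add <- function(hyp, test, model, response, comps, component, full,
                    reduced) {
        lrt <- likelihoodRatioTest(full, reduced)
        rows[[length(rows) + 1L]] <<- data.frame(
            hypothesis = hyp, test = test, model = model,
            response = response, compositions = comps,
            component = component, chisq = lrt$chisq, df = lrt$df,
            p = lrt$p, stringsAsFactors = FALSE)
    }
    ## H1: compositions 1-4, model 1, total DMW
    m_int <- fitYieldModel(yields, 1, "total", "L * T")
    m_add <- fitYieldModel(yields, 1, "total", "L + T")
    add("H1", "a", 1, "total", "1-4", "LxT", m_int, m_add)
    add("H1", "b", 1, "total", "1-4", "L", m_add,
        fitYieldModel(yields, 1, "total", "T"))
    add("H1", "c", 1, "total", "1-4", "T", m_add,
        fitYieldModel(yields, 1, "total", "L"))
    ## H2 (compositions 3-5, model 2) and H3 (5-7, model 3): total, grass
    ## and clover DMW as tests a, b, c
    responses <- c(a = "total", b = "grass", c = "clover")
    for (t in names(responses)) {
        resp <- responses[[t]]
        add("H2", t, 2, resp, "3-5", "L",
            fitYieldModel(yields, 2, resp, "L"),
            fitYieldModel(yields, 2, resp, "1"))
        add("H3", t, 3, resp, "5-7", "T",
            fitYieldModel(yields, 3, resp, "T"),
            fitYieldModel(yields, 3, resp, "1"))
    }
    out <- do.call(rbind, rows)
    out <- out[order(out$hypothesis, out$test), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Read a deposited yield table
#'
#' Reads an annual (or per-cut) yield TSV and maps it onto the package's
#' yield layout. Column names are auto-detected case-insensitively among
#' plausible spellings (`seed_composition`/`composition`/`comp`,
#' `replicate`/`rep`/`block`, `year`, optional `cut`, and the DMW columns
#' `dmw_total`/`total`/`yield`, `dmw_grass`/`grass`,
#' `dmw_clover`/`clover`); unrecognized layouts fail loudly. Per-cut rows
#' are summed to annual totals.
#'
#' @param path TSV file path.
#' @return data.frame in the [simulateYield()] layout (annual rows).
#' @export
readYieldTable <- function(path) {
    tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
    ln <- tolower(names(tab))
    pick <- function(cands, what, required = TRUE) {
        hit <- which(ln %in% cands)
        if (length(hit) == 0L) {
            if (required)
                stop("cannot locate the ", what, " column; looked for: ",
                     paste(cands, collapse = ", "))
            return(NA_integer_)
        }
        hit[1L]
    }
    ic <- pick(c("seed_composition", "seedcomposition", "composition",
                 "seed_comp", "comp"), "seed-composition")
    ir <- pick(c("replicate", "rep", "block"), "replicate")
    iy <- pick(c("year", "yr"), "year")
    icut <- pick(c("cut", "harvest"), "cut", required = FALSE)
    it <- pick(c("dmw_total", "total_dmw", "dmw", "total", "yield",
                 "yield_total", "total_yield"), "total-DMW")
    ig <- pick(c("dmw_grass", "grass_dmw", "grass", "yield_grass"),
               "grass-DMW", required = FALSE)
    icl <- pick(c("dmw_clover", "clover_dmw", "clover", "yield_clover"),
                "clover-DMW", required = FALSE)
    out <- data.frame(composition = as.integer(tab[[ic]]),
                      replicate = as.character(tab[[ir]]),
                      year = as.integer(tab[[iy]]),
                      dmw_total = as.numeric(tab[[it]]),
                      stringsAsFactors = FALSE)
    out$dmw_grass <- if (!is.na(ig)) as.numeric(tab[[ig]]) else NA_real_
    out$dmw_clover <- if (!is.na(icl)) as.numeric(tab[[icl]])
                      else NA_real_
    if (!is.na(icut)) {
        agg <- stats::aggregate(
            out[c("dmw_total", "dmw_grass", "dmw_clover")],
            by = out[c("composition", "replicate", "year")], FUN = sum)
        out <- agg
    }
    if (any(is.na(out$composition)) ||
        any(out$composition < 1L | out$composition > 7L))
        stop("seed compositions outside 1..7 in yield table")
    out[order(out$composition, out$replicate, out$year), , drop = FALSE]
}
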